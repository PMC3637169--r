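#' @import methods
#' @importFrom stats rpois rgeom runif setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

#' @rdname GeneModel-class
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))

#' @rdname GeneModel-class
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @rdname GeneModel-class
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname ScoreVector-class
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))

#' @rdname ScoreVector-class
#' @export
setGeneric("scoreRole", function(x) standardGeneric("scoreRole"))

#' @rdname ScoreVector-class
#' @export
setGeneric("isEmptyScore", function(x) standardGeneric("isEmptyScore"))

#' @rdname LesionSet-class
#' @export
setGeneric("sampleName", function(x) standardGeneric("sampleName"))

#' @rdname LesionSet-class
#' @export
setGeneric("alterationType", function(x) standardGeneric("alterationType"))

#' @rdname LesionSet-class
#' @export
setGeneric("lesionList", function(x) standardGeneric("lesionList"))

#' @rdname PriorTrace-class
#' @export
setGeneric("finalPrior", function(x) standardGeneric("finalPrior"))

#' @rdname PriorTrace-class
#' @export
setGeneric("klSteps", function(x) standardGeneric("klSteps"))

#' @rdname PriorTrace-class
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname PriorTrace-class
#' @export
setGeneric("nIterations", function(x) standardGeneric("nIterations"))
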