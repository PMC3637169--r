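#' GeneModel: an ordered gene universe
#'
#' A \code{GeneModel} holds the gene universe over which all score
#' distributions are defined: one named, non-overlapping-symbol record per
#' gene, sorted in genome order (chromosome, then start).  The position of a
#' gene in this order is its genome index, used for region construction and
#' deterministic tie-breaking.  Intervals are stored as a
#' \linkS4class{GRanges}; readers convert external conventions (0-based
#' half-open BED, 1-based refFlat) on ingest.
#'
#' @slot genes A \code{GRanges} with a \code{symbol} metadata column, sorted
#'   in genome order; symbols are unique.
#'
#' @param x A \code{GeneModel}.
#' @return \code{geneSymbols} returns the character vector of symbols in
#'   genome order; \code{nGenes} the number of genes; \code{geneRanges} the
#'   underlying \code{GRanges}.
#' @seealso [readGeneModel()], [genesInInterval()]
#' @aliases geneSymbols nGenes geneRanges
#' @export
setClass("GeneModel", representation(genes = "GRanges"))

setValidity("GeneModel", function(object) {
    gr <- object@genes
    msg <- character()
    if (length(gr) == 0L)
        msg <- c(msg, "gene model contains no genes")
    if (is.null(gr$symbol) || !is.character(gr$symbol))
        msg <- c(msg, "genes must carry a character 'symbol' metadata column")
    else if (anyDuplicated(gr$symbol))
        msg <- c(msg, "gene symbols must be unique")
    if (any(GenomicRanges::width(gr) < 1L))
        msg <- c(msg, "all genes must have positive width")
    if (length(msg)) msg else TRUE
})

#' @rdname GeneModel-class
#' @export
setMethod("geneSymbols", "GeneModel", function(x) x@genes$symbol)

#' @rdname GeneModel-class
#' @export
setMethod("nGenes", "GeneModel", function(x) length(x@genes))

#' @rdname GeneModel-class
#' @export
setMethod("geneRanges", "GeneModel", function(x) x@genes)

setMethod("show", "GeneModel", function(object) {
    chroms <- unique(as.character(GenomicRanges::seqnames(object@genes)))
    cat("GeneModel with", length(object@genes), "genes on",
        length(chroms), "chromosome(s)\n")
    cat("  chromosomes:", paste(utils::head(chroms, 8), collapse = ", "),
        if (length(chroms) > 8) "..." else "", "\n")
})

#' LesionSet: the disjoint lesions of one alteration type in one sample
#'
#' One somatic lesion is an amplitude \eqn{C} (copies deviated from ploidy;
#' 1 for a point mutation) together with the non-empty set \eqn{N} of genes
#' it alters.  A \code{LesionSet} collects all lesions of a single type
#' (gain, deletion or mutation) observed in one sample; their gene sets are
#' pairwise disjoint by construction (overlapping calls are merged upstream).
#'
#' @slot sample Sample identifier.
#' @slot type One of \code{"gain"}, \code{"deletion"}, \code{"mutation"}.
#' @slot lesions A list; each element is a \code{list(amplitude=, genes=)}
#'   with \code{amplitude} a positive number and \code{genes} a character
#'   vector of gene symbols.
#'
#' @param x A \code{LesionSet}.
#' @aliases sampleName alterationType lesionList
#' @export
setClass("LesionSet", representation(
    sample = "character", type = "character", lesions = "list"))

setValidity("LesionSet", function(object) {
    msg <- character()
    if (length(object@sample) != 1L)
        msg <- c(msg, "sample must be a single string")
    if (!object@type %in% c("gain", "deletion", "mutation"))
        msg <- c(msg, "type must be 'gain', 'deletion' or 'mutation'")
    for (les in object@lesions) {
        if (!is.list(les) || is.null(les$amplitude) || is.null(les$genes)) {
            msg <- c(msg, "each lesion needs 'amplitude' and 'genes'")
            break
        }
        if (!is.numeric(les$amplitude) || les$amplitude <= 0) {
            msg <- c(msg, "lesion amplitudes must be positive")
            break
        }
        if (length(les$genes) == 0L) {
            msg <- c(msg, "lesion gene sets must be non-empty")
            break
        }
    }
    allGenes <- unlist(lapply(object@lesions, `[[`, "genes"), use.names = FALSE)
    if (anyDuplicated(allGenes))
        msg <- c(msg, "lesion gene sets must be pairwise disjoint")
    if (length(msg)) msg else TRUE
})

#' Construct a LesionSet
#'
#' @param sample Sample identifier.
#' @param type Alteration type: \code{"gain"}, \code{"deletion"} or
#'   \code{"mutation"}.
#' @param lesions List of \code{list(amplitude=, genes=)} elements with
#'   pairwise-disjoint gene sets.
#' @return A \linkS4class{LesionSet}.
#' @export
LesionSet <- function(sample, type, lesions = list()) {
    new("LesionSet", sample = as.character(sample), type = type,
        lesions = lesions)
}

#' @rdname LesionSet-class
#' @export
setMethod("sampleName", "LesionSet", function(x) x@sample)

#' @rdname LesionSet-class
#' @export
setMethod("alterationType", "LesionSet", function(x) x@type)

#' @rdname LesionSet-class
#' @export
setMethod("lesionList", "LesionSet", function(x) x@lesions)

setMethod("show", "LesionSet", function(object) {
    sizes <- vapply(object@lesions, function(l) length(l$genes), integer(1))
    cat("LesionSet:", object@type, "lesions of sample", object@sample, "\n")
    cat("  ", length(object@lesions), "lesion(s) covering ", sum(sizes),
        " gene(s)\n", sep = "")
})

#' ScoreVector: a normalized score distribution over genes
#'
#' Scores produced anywhere in the pipeline are probability distributions
#' over the gene universe: non-negative, summing to 1 (within 1e-9).  The
#' one exception is the all-zero "empty" vector returned for a sample none
#' of whose lesions carries prior mass; empty vectors are excluded from
#' aggregation.  The \code{role} records what the distribution is
#' (prior, per-sample posterior, aggregated, combined, integrated).
#'
#' @slot values Named numeric vector over the gene universe, genome order.
#' @slot role Character label for the vector's role in the pipeline.
#'
#' @param x A \code{ScoreVector}.
#' @aliases scoreValues scoreRole isEmptyScore
#' @export
setClass("ScoreVector", representation(values = "numeric", role = "character"))

setValidity("ScoreVector", function(object) {
    v <- object@values
    msg <- character()
    if (is.null(names(v)) || anyDuplicated(names(v)))
        msg <- c(msg, "values must be named with unique gene symbols")
    if (any(!is.finite(v)))
        msg <- c(msg, "values must be finite")
    else if (any(v < 0))
        msg <- c(msg, "values must be non-negative")
    else {
        s <- sum(v)
        if (s != 0 && abs(s - 1) > 1e-9)
            msg <- c(msg, sprintf("values must sum to 1 (got %.12f)", s))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a ScoreVector
#'
#' @param values Named non-negative numeric vector summing to 1 (or all
#'   zero for an empty vector).
#' @param role Role label.
#' @return A \linkS4class{ScoreVector}.
#' @export
ScoreVector <- function(values, role = "aggregated") {
    new("ScoreVector", values = values, role = role)
}

#' @rdname ScoreVector-class
#' @export
setMethod("scoreValues", "ScoreVector", function(x) x@values)

#' @rdname ScoreVector-class
#' @export
setMethod("scoreRole", "ScoreVector", function(x) x@role)

#' @rdname ScoreVector-class
#' @export
setMethod("isEmptyScore", "ScoreVector", function(x) sum(x@values) == 0)

setMethod("show", "ScoreVector", function(object) {
    v <- object@values
    cat("ScoreVector (", object@role, ") over ", length(v), " genes, ",
        sum(v > 0), " with positive score\n", sep = "")
    if (any(v > 0)) {
        top <- sort(v[v > 0], decreasing = TRUE)
        top <- utils::head(top, 5)
        cat("  top:", paste(sprintf("%s=%.4g", names(top), top),
                            collapse = ", "), "\n")
    }
})

#' PriorTrace: the trajectory of the empirical-prior iteration
#'
#' Records the sequence of distributions \eqn{P_0, P_1, \ldots} produced by
#' iterating the empirical-prior update, the Kullback-Leibler step sizes
#' between consecutive iterates (in bits), and whether the iteration reached
#' the stopping tolerance.
#'
#' @slot iterates List of \linkS4class{ScoreVector}s, \eqn{P_0} first;
#'   either the full sequence or just \eqn{P_0} and the final iterate
#'   when the trace was built with \code{keepIterates = FALSE}.
#' @slot kl Numeric vector; \code{kl[j]} is \eqn{KL(P_j \| P_{j-1})}.
#' @slot converged Whether the last KL step fell below \code{tol}.
#' @slot tol The stopping tolerance in bits.
#'
#' @param x A \code{PriorTrace}.
#' @aliases finalPrior klSteps isConverged nIterations
#' @export
setClass("PriorTrace", representation(
    iterates = "list", kl = "numeric", converged = "logical",
    tol = "numeric"))

setValidity("PriorTrace", function(object) {
    msg <- character()
    nIt <- length(object@iterates)
    if (nIt != length(object@kl) + 1L && nIt != 2L)
        msg <- c(msg, "need one more iterate than KL steps (or a compact P0/final pair)")
    if (any(object@kl < 0))
        msg <- c(msg, "KL steps must be non-negative")
    n <- length(object@kl)
    if (n > 0L && object@converged != (object@kl[n] < object@tol))
        msg <- c(msg, "converged flag inconsistent with last KL step")
    if (length(msg)) msg else TRUE
})

#' @rdname PriorTrace-class
#' @export
setMethod("finalPrior", "PriorTrace",
          function(x) x@iterates[[length(x@iterates)]])

#' @rdname PriorTrace-class
#' @export
setMethod("klSteps", "PriorTrace", function(x) x@kl)

#' @rdname PriorTrace-class
#' @export
setMethod("isConverged", "PriorTrace", function(x) x@converged)

#' @rdname PriorTrace-class
#' @export
setMethod("nIterations", "PriorTrace", function(x) length(x@kl))

setMethod("show", "PriorTrace", function(object) {
    n <- length(object@kl)
    cat("PriorTrace:", n, "update(s),",
        if (object@converged) "converged" else "not converged",
        sprintf("(tol %g bits)\n", object@tol))
    if (n > 0)
        cat("  final KL step:", format(object@kl[n], digits = 4), "bits\n")
})
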