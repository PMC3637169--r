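#' Default protein-changing mutation classes
#'
#' The MAF variant classifications kept by default when reading mutation
#' calls: classes that change the protein product.
#'
#' @return Character vector of MAF \code{Variant_Classification} values.
#' @export
proteinChangingClasses <- function() {
    c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
      "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
      "Splice_Site", "Translation_Start_Site")
}

#' Read segmented copy-number calls (SEG)
#'
#' Reads a tab-separated SEG-like table with header and columns
#' \code{sample}, \code{chromosome}, \code{start}, \code{end},
#' \code{value}.  SEG coordinates are 1-based inclusive and are converted
#' to the internal 0-based half-open convention.  In \code{log2ratio} mode
#' the value column is converted to absolute copies as
#' \eqn{ploidy \cdot 2^{ratio}}.
#'
#' @param path Path to the SEG file.
#' @param mode \code{"absolute"} (value is absolute copy number) or
#'   \code{"log2ratio"}.
#' @param ploidy Baseline copy number (default 2).
#' @return A data.frame with columns \code{sample}, \code{chromosome},
#'   \code{start}, \code{end} (0-based half-open) and \code{cn} (absolute
#'   copy number).
#' @export
readSeg <- function(path, mode = c("absolute", "log2ratio"), ploidy = 2) {
    mode <- match.arg(mode)
    stopifnot(ploidy >= 1)
    if (!file.exists(path))
        stop("SEG file not found: ", path, call. = FALSE)
    df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                     check.names = FALSE)
    names(df) <- tolower(names(df))
    required <- c("sample", "chromosome", "start", "end", "value")
    missing <- setdiff(required, names(df))
    if (length(missing))
        stop("SEG file missing required column(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    if (nrow(df) == 0L)
        return(data.frame(sample = character(), chromosome = character(),
                          start = numeric(), end = numeric(),
                          cn = numeric(), stringsAsFactors = FALSE))
    start <- suppressWarnings(as.numeric(df$start))
    end <- suppressWarnings(as.numeric(df$end))
    value <- suppressWarnings(as.numeric(df$value))
    bad <- which(is.na(start) | is.na(end) | is.na(value))
    if (length(bad))
        stop(sprintf("SEG line %d: non-numeric start/end/value",
                     bad[1] + 1L), call. = FALSE)
    bad <- which(end < start)
    if (length(bad))
        stop(sprintf("SEG line %d: end < start", bad[1] + 1L), call. = FALSE)
    cn <- if (mode == "log2ratio") ploidy * 2^value else value
    if (any(!is.finite(cn)))
        stop("non-finite copy-number value after conversion", call. = FALSE)
    data.frame(sample = as.character(df$sample),
               chromosome = as.character(df$chromosome),
               start = start - 1, end = end,
               cn = cn, stringsAsFactors = FALSE)
}

#' Discretize a copy-number value into an alteration call
#'
#' Converts an absolute copy number into an alteration type and integer
#' amplitude \eqn{D = } round\eqn{(|cn - ploidy|)} (half away from zero):
#' a loss of two copies has amplitude 2, a loss of one copy amplitude 1, a
#' gain of one copy amplitude 1, and so on.  Values rounding to the
#' baseline yield type \code{"none"}; deletion amplitudes are capped at
#' the ploidy.
#'
#' @param cn Numeric vector of absolute copy numbers (>= 0).
#' @param ploidy Baseline copy number (default 2).
#' @return A data.frame with columns \code{type} (\code{"gain"},
#'   \code{"deletion"} or \code{"none"}) and \code{amplitude} (integer,
#'   0 for \code{"none"}).
#' @examples
#' discretizeAmplitude(c(0, 1, 3, 2.2))
#' @export
discretizeAmplitude <- function(cn, ploidy = 2) {
    stopifnot(is.numeric(cn), all(cn >= 0), ploidy >= 1)
    dev <- cn - ploidy
    d <- floor(abs(dev) + 0.5)  # round half up, not banker's
    type <- ifelse(d == 0, "none", ifelse(dev > 0, "gain", "deletion"))
    d <- ifelse(type == "deletion", pmin(d, ploidy), d)
    data.frame(type = type, amplitude = as.integer(d),
               stringsAsFactors = FALSE)
}

#' Read somatic mutation calls
#'
#' Reads per-sample mutation calls either from a MAF (columns
#' \code{Hugo_Symbol}, \code{Tumor_Sample_Barcode},
#' \code{Variant_Classification}; other columns ignored) or from a minimal
#' TSV with columns \code{sample}, \code{gene} and optionally
#' \code{classification}.  Records whose classification is not in
#' \code{keepClasses} are dropped (when no classification column exists all
#' records are kept).  When a \linkS4class{GeneModel} is supplied, records
#' for symbols absent from the model are dropped with a message.
#'
#' @param path Path to the mutation file.
#' @param format \code{"maf"} or \code{"tsv"}.
#' @param keepClasses Classifications to keep; default the protein-changing
#'   classes of [proteinChangingClasses()].
#' @param model Optional \linkS4class{GeneModel} used to harmonize symbols.
#' @return A data.frame with columns \code{sample}, \code{gene},
#'   \code{classification} (\code{NA} when absent from the input).
#' @export
readMutations <- function(path, format = c("maf", "tsv"),
                          keepClasses = proteinChangingClasses(),
                          model = NULL) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop("mutation file not found: ", path, call. = FALSE)
    df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                     check.names = FALSE, comment.char = "#")
    if (format == "maf") {
        required <- c("Hugo_Symbol", "Tumor_Sample_Barcode",
                      "Variant_Classification")
        missing <- setdiff(required, names(df))
        if (length(missing))
            stop("MAF missing required column(s): ",
                 paste(missing, collapse = ", "), call. = FALSE)
        out <- data.frame(sample = as.character(df$Tumor_Sample_Barcode),
                          gene = as.character(df$Hugo_Symbol),
                          classification =
                              as.character(df$Variant_Classification),
                          stringsAsFactors = FALSE)
        out <- out[out$classification %in% keepClasses, , drop = FALSE]
    } else {
        names(df) <- tolower(names(df))
        missing <- setdiff(c("sample", "gene"), names(df))
        if (length(missing))
            stop("mutation TSV missing required column(s): ",
                 paste(missing, collapse = ", "), call. = FALSE)
        cls <- if ("classification" %in% names(df))
            as.character(df$classification) else NA_character_
        out <- data.frame(sample = as.character(df$sample),
                          gene = as.character(df$gene),
                          classification = cls, stringsAsFactors = FALSE)
        if ("classification" %in% names(df))
            out <- out[out$classification %in% keepClasses, , drop = FALSE]
    }
    if (!is.null(model)) {
        known <- out$gene %in% geneSymbols(model)
        if (any(!known))
            message(sum(!known), " mutation record(s) for symbols absent ",
                    "from the gene model dropped")
        out <- out[known, , drop = FALSE]
    }
    rownames(out) <- NULL
    out
}

#' Keep only recurrently mutated genes
#'
#' Collapses per-gene per-sample duplicate records to one, then keeps
#' exactly the genes mutated in at least \code{minSamples} distinct
#' samples.  Recurrence is counted over samples, not over individual
#' mutations: three mutations of a gene in one sample do not make it
#' recurrent.
#'
#' @param records Mutation record data.frame from [readMutations()].
#' @param minSamples Minimum number of distinct mutated samples (default 2).
#' @return The filtered, per-sample de-duplicated record data.frame.
#' @export
filterRecurrent <- function(records, minSamples = 2) {
    stopifnot(minSamples >= 1)
    if (nrow(records) == 0L)
        return(records)
    dedup <- records[!duplicated(records[c("sample", "gene")]), ,
                     drop = FALSE]
    nSamp <- table(dedup$gene)
    keep <- names(nSamp)[nSamp >= minSamples]
    out <- dedup[dedup$gene %in% keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}
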