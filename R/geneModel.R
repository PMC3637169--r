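#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   pintersect
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

## Natural chromosome order: chr1 < chr2 < ... < chr22 < others (alphabetical).
chromRank <- function(chrom) {
    stripped <- sub("^chr", "", chrom)
    num <- suppressWarnings(as.integer(stripped))
    key <- ifelse(is.na(num), .Machine$integer.max, num)
    lev <- unique(stripped[order(key, stripped)])
    match(stripped, lev)
}

isAutosome <- function(chrom) {
    stripped <- sub("^chr", "", chrom)
    !is.na(suppressWarnings(as.integer(stripped)))
}

## Build a GeneModel from a table of (symbol, chromosome, start, end) in
## 0-based half-open coordinates, applying the duplicate-symbol policy and
## sorting into genome order.
geneModelFromTable <- function(df, autosomesOnly = TRUE) {
    if (autosomesOnly) {
        keep <- isAutosome(df$chromosome)
        df <- df[keep, , drop = FALSE]
    }
    if (nrow(df) == 0L)
        stop("no genes", call. = FALSE)
    ## duplicate symbols: same chromosome -> union span; otherwise drop
    if (anyDuplicated(df$symbol)) {
        dup <- unique(df$symbol[duplicated(df$symbol)])
        dropped <- character()
        pieces <- list(df[!df$symbol %in% dup, , drop = FALSE])
        for (sym in dup) {
            rows <- df[df$symbol == sym, , drop = FALSE]
            if (length(unique(rows$chromosome)) > 1L) {
                dropped <- c(dropped, sym)
            } else {
                pieces[[length(pieces) + 1L]] <- data.frame(
                    symbol = sym, chromosome = rows$chromosome[1],
                    start = min(rows$start), end = max(rows$end),
                    stringsAsFactors = FALSE)
            }
        }
        if (length(dropped))
            warning(length(dropped), " symbol(s) duplicated across ",
                    "chromosomes dropped: ",
                    paste(utils::head(dropped, 5), collapse = ", "),
                    call. = FALSE)
        df <- do.call(rbind, pieces)
        if (nrow(df) == 0L)
            stop("no genes", call. = FALSE)
    }
    o <- order(chromRank(df$chromosome), df$start, df$end, df$symbol)
    df <- df[o, , drop = FALSE]
    gr <- GRanges(
        seqnames = df$chromosome,
        ranges = IRanges(start = df$start + 1L, end = df$end),
        symbol = df$symbol)
    new("GeneModel", genes = gr)
}

#' Read a gene model from BED or refFlat
#'
#' Loads the gene universe used by every downstream score.  BED input is
#' read as 0-based half-open with the symbol in column 4; refFlat as the
#' standard 11-column table with a 1-based transcript start, converted on
#' read.  Records sharing a symbol on one chromosome are collapsed to the
#' union span; symbols duplicated across chromosomes are dropped with a
#' warning, so that score vectors have exactly one entry per symbol.
#'
#' @param path Path to the annotation file (tab-separated, no header).
#' @param format \code{"bed"} or \code{"refflat"}.
#' @param autosomesOnly Drop non-autosomal chromosomes (default TRUE).
#' @return A \linkS4class{GeneModel}.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t200\tTP53", "chr1\t400\t600\tMYC"), bed)
#' gm <- readGeneModel(bed)
#' geneSymbols(gm)
#' @export
readGeneModel <- function(path, format = c("bed", "refflat"),
                          autosomesOnly = TRUE) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop("gene model file not found: ", path, call. = FALSE)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    lines <- lines[!startsWith(lines, "#")]
    if (length(lines) == 0L)
        stop("no genes", call. = FALSE)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    minCols <- if (format == "bed") 4L else 11L
    rows <- vector("list", length(fields))
    for (i in seq_along(fields)) {
        f <- fields[[i]]
        if (length(f) < minCols)
            stop(sprintf("line %d: expected >= %d columns, got %d",
                         i, minCols, length(f)), call. = FALSE)
        if (format == "bed") {
            start <- suppressWarnings(as.numeric(f[2]))
            end <- suppressWarnings(as.numeric(f[3]))
            sym <- f[4]
            chrom <- f[1]
        } else {
            ## refFlat: geneName name chrom strand txStart txEnd ...
            start <- suppressWarnings(as.numeric(f[5])) - 1
            end <- suppressWarnings(as.numeric(f[6]))
            sym <- f[1]
            chrom <- f[3]
        }
        if (is.na(start) || is.na(end))
            stop(sprintf("line %d: non-numeric coordinates", i),
                 call. = FALSE)
        if (start >= end)
            stop(sprintf("line %d: start >= end for gene '%s'", i, sym),
                 call. = FALSE)
        rows[[i]] <- data.frame(symbol = sym, chromosome = chrom,
                                start = start, end = end,
                                stringsAsFactors = FALSE)
    }
    geneModelFromTable(do.call(rbind, rows), autosomesOnly = autosomesOnly)
}

#' Genes overlapping a genomic interval
#'
#' Maps an interval (0-based half-open, the package's internal coordinate
#' convention) to the gene symbols it covers.  A gene counts as contained
#' when it overlaps the interval by at least one base pair and by at least
#' \code{minOverlapFraction} of the gene's own length.  This realizes the
#' "length in genes" of a copy-number lesion.
#'
#' @param model A \linkS4class{GeneModel}.
#' @param chromosome Chromosome name.
#' @param start,end Interval bounds, 0-based half-open.
#' @param minOverlapFraction Minimum overlapped fraction of the gene's
#'   length, in \[0, 1\]; 0 (default) means any overlap counts.
#' @return Character vector of gene symbols in genome order.
#' @export
genesInInterval <- function(model, chromosome, start, end,
                            minOverlapFraction = 0) {
    stopifnot(is(model, "GeneModel"), start < end,
              minOverlapFraction >= 0, minOverlapFraction <= 1)
    gr <- model@genes
    if (!chromosome %in% as.character(unique(seqnames(gr)))) {
        warning("unknown chromosome: ", chromosome, call. = FALSE)
        return(character())
    }
    query <- GRanges(chromosome, IRanges(start = start + 1L, end = end))
    hits <- findOverlaps(query, gr)
    idx <- subjectHits(hits)
    if (length(idx) == 0L)
        return(character())
    ov <- pintersect(gr[idx], rep(query, length(idx)))
    frac <- width(ov) / width(gr[idx])
    idx <- idx[frac >= minOverlapFraction & width(ov) > 0]
    gr$symbol[sort(idx)]
}
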