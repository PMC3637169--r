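#' Group top-tier genes into genomic regions with leader genes
#'
#' Genes in tiers up to \code{maxTier} are placed on the genome and linked
#' into regions: two selected genes on the same chromosome belong to the
#' same region when at most \code{gapGenes} unselected genes lie between
#' them in genome order.  Each region's leader is its highest-scoring
#' member (ties broken by smaller genomic start coordinate); regions are
#' ranked by leader score, descending, and truncated to the top
#' \code{topK}.  The tier-cutoff-plus-gene-gap construction is this
#' package's own definition of a region and is fully parameterized.
#'
#' @param p The \linkS4class{ScoreVector} the tiers were computed from.
#' @param tiers Tier table from [assignTiers()].
#' @param model A \linkS4class{GeneModel}.
#' @param maxTier Highest tier included (default 1).
#' @param gapGenes Maximum number of unselected genes bridged within a
#'   region (default 10).
#' @param topK Number of regions reported (default 25).
#' @return A data.frame with columns \code{rank}, \code{chromosome},
#'   \code{start}, \code{end} (span from first member's start to last
#'   member's end, 0-based half-open), \code{n_genes}, \code{members}
#'   (comma-joined, genome order), \code{leader}, \code{leader_score}.
#' @export
buildRegions <- function(p, tiers, model, maxTier = 1, gapGenes = 10,
                         topK = 25) {
    stopifnot(is(model, "GeneModel"), maxTier >= 1, gapGenes >= 0, topK >= 1)
    v <- scoreValues(p)
    selected <- tiers$gene[tiers$tier <= maxTier]
    empty <- data.frame(rank = integer(), chromosome = character(),
                        start = numeric(), end = numeric(),
                        n_genes = integer(), members = character(),
                        leader = character(), leader_score = numeric(),
                        stringsAsFactors = FALSE)
    if (length(selected) == 0L) {
        warning("no genes selected for region construction", call. = FALSE)
        return(empty)
    }
    gr <- geneRanges(model)
    idx <- match(selected, gr$symbol)
    o <- order(idx)
    idx <- idx[o]
    chrom <- as.character(GenomicRanges::seqnames(gr))[idx]
    ## a new region starts at a chromosome change or a gap of more than
    ## gapGenes unselected genes in genome order
    newRegion <- c(TRUE, chrom[-1] != chrom[-length(chrom)] |
                         diff(idx) - 1L > gapGenes)
    regionId <- cumsum(newRegion)
    regions <- lapply(split(idx, regionId), function(members) {
        syms <- gr$symbol[members]
        scores <- v[syms]
        best <- which(scores == max(scores))
        if (length(best) > 1L) {
            starts <- GenomicRanges::start(gr)[members[best]]
            best <- best[which.min(starts)]
        }
        data.frame(
            chromosome = as.character(
                GenomicRanges::seqnames(gr))[members[1]],
            start = GenomicRanges::start(gr)[members[1]] - 1,
            end = GenomicRanges::end(gr)[members[length(members)]],
            n_genes = length(members),
            members = paste(syms, collapse = ","),
            leader = syms[best],
            leader_score = unname(scores[best]),
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, regions)
    o <- order(-out$leader_score, chromRank(out$chromosome), out$start)
    out <- out[o, , drop = FALSE]
    out <- utils::head(out, topK)
    out <- cbind(rank = seq_len(nrow(out)), out)
    rownames(out) <- NULL
    out
}
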