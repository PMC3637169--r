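## Merge lesions whose gene sets intersect: union genes, max amplitude.
## Overlapping same-type calls usually re-describe one event, so the max
## (not the sum) is kept.  Union-find over a gene -> lesion claim table.
mergeLesions <- function(lesions) {
    if (length(lesions) <= 1L)
        return(lesions)
    parent <- seq_along(lesions)
    find <- function(i) {
        while (parent[i] != i) i <- parent[i]
        i
    }
    claim <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_along(lesions)) {
        for (g in lesions[[i]]$genes) {
            j <- mget(g, envir = claim, ifnotfound = NA)[[1]]
            if (is.na(j)) {
                assign(g, i, envir = claim)
            } else {
                ri <- find(i); rj <- find(j)
                if (ri != rj) parent[ri] <- rj
            }
        }
    }
    roots <- vapply(seq_along(lesions), find, integer(1))
    out <- lapply(split(seq_along(lesions), roots), function(idx) {
        list(amplitude = max(vapply(lesions[idx], `[[`, numeric(1),
                                    "amplitude")),
             genes = unique(unlist(lapply(lesions[idx], `[[`, "genes"),
                                   use.names = FALSE)))
    })
    names(out) <- NULL
    out
}

#' Build per-sample gain and deletion lesion sets from segments
#'
#' Turns segmented copy-number calls into the lesion representation the
#' scores are defined on.  Each altered segment (nonzero amplitude after
#' [discretizeAmplitude()]) becomes a lesion whose gene set is the genes it
#' overlaps; segments covering no gene are dropped.  Within one sample and
#' alteration type, lesions whose gene sets intersect are merged
#' (gene-set union, maximum amplitude), so the disjointness invariant of
#' \linkS4class{LesionSet} holds on output.
#'
#' @param segments Segment data.frame from [readSeg()].
#' @param model A \linkS4class{GeneModel}.
#' @param ploidy Baseline copy number (default 2).
#' @param minOverlapFraction Passed to [genesInInterval()].
#' @return A named list (one element per sample) of lists with components
#'   \code{gain} and \code{deletion}, each a \linkS4class{LesionSet}
#'   (possibly with zero lesions).
#' @export
buildLesionSets <- function(segments, model, ploidy = 2,
                            minOverlapFraction = 0) {
    stopifnot(is(model, "GeneModel"))
    disc <- discretizeAmplitude(segments$cn, ploidy = ploidy)
    segments$type <- disc$type
    segments$amplitude <- disc$amplitude
    segments <- segments[segments$type != "none", , drop = FALSE]
    samples <- unique(segments$sample)
    knownChrom <- as.character(unique(GenomicRanges::seqnames(
        geneRanges(model))))
    out <- vector("list", length(samples))
    names(out) <- samples
    for (s in samples) {
        sub <- segments[segments$sample == s, , drop = FALSE]
        bySample <- list()
        for (type in c("gain", "deletion")) {
            rows <- sub[sub$type == type, , drop = FALSE]
            lesions <- list()
            for (i in seq_len(nrow(rows))) {
                if (!rows$chromosome[i] %in% knownChrom)
                    next
                genes <- genesInInterval(model, rows$chromosome[i],
                                         rows$start[i], rows$end[i],
                                         minOverlapFraction)
                if (length(genes) == 0L)
                    next
                lesions[[length(lesions) + 1L]] <-
                    list(amplitude = rows$amplitude[i], genes = genes)
            }
            bySample[[type]] <- LesionSet(s, type, mergeLesions(lesions))
        }
        out[[s]] <- bySample
    }
    out
}

#' Build per-sample mutation lesion sets
#'
#' Every mutated gene in a sample becomes a single-gene lesion.  In the
#' default \code{"binary"} mode the amplitude is 1 regardless of how many
#' mutations hit the gene; in \code{"count"} mode the amplitude is the
#' number of records for that gene and sample.
#'
#' @param records Mutation record data.frame (typically after
#'   [filterRecurrent()]).
#' @param mode \code{"binary"} or \code{"count"}.
#' @return A named list of \linkS4class{LesionSet}s of type
#'   \code{"mutation"}, one per sample.
#' @export
mutationLesionSets <- function(records, mode = c("binary", "count")) {
    mode <- match.arg(mode)
    if (nrow(records) == 0L)
        return(structure(list(), names = character()))
    counts <- table(records$sample, records$gene)
    samples <- rownames(counts)
    out <- vector("list", length(samples))
    names(out) <- samples
    for (s in samples) {
        hits <- counts[s, ]
        genes <- colnames(counts)[hits > 0]
        lesions <- lapply(genes, function(g) {
            list(amplitude = if (mode == "count") as.numeric(counts[s, g])
                 else 1,
                 genes = g)
        })
        out[[s]] <- LesionSet(s, "mutation", lesions)
    }
    out
}
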