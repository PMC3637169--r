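#' Configuration for a synthetic tumor cohort
#'
#' Describes the generative model used for end-to-end validation: a
#' regular genome of \code{nGenes} genes evenly spaced over
#' \code{nChromosomes} chromosomes; per sample a Poisson number of
#' passenger copy-number lesions at uniform positions with
#' geometric sizes; implanted driver genes hit by focal lesions of their
#' own type with probability \code{hitProb}; and Bernoulli point
#' mutations at a low passenger rate per gene plus an elevated rate at
#' each driver.  Defaults define the package's standard recovery
#' scenario.
#'
#' @param nGenes Number of genes in the universe (default 2000).
#' @param nChromosomes Number of chromosomes (default 8).
#' @param nSamples Number of tumor samples (default 50).
#' @param drivers data.frame with columns \code{symbol}, \code{type}
#'   (\code{"gain"}/\code{"deletion"}), \code{hitProb},
#'   \code{focalSizeMean}; by default 5 drivers evenly spread over the
#'   genome, alternating gain and deletion, \code{hitProb} 0.4 and mean
#'   focal size 3 genes.
#' @param passengerLesionsPerSample Poisson mean of passenger lesions per
#'   sample (default 10).
#' @param lesionSizeMean Mean passenger lesion size in genes, geometric
#'   (default 50).
#' @param amplitudeWeights Probabilities of amplitude 1 and 2 for any
#'   lesion (default 0.7/0.3).
#' @param passengerMutationRate Per-gene per-sample mutation probability
#'   (default 0.002).
#' @param driverMutationRate Per-driver per-sample mutation probability
#'   (default 0.15).
#' @param ploidy Baseline copy number (default 2).
#' @param geneLength,geneSpacing Gene body length and start-to-start
#'   spacing in base pairs.
#' @param seed Integer seed; all randomness in [simulateCohort()] derives
#'   from it.
#' @return A \code{SimConfig} object (a validated list).
#' @export
simConfig <- function(nGenes = 2000, nChromosomes = 8, nSamples = 50,
                      drivers = NULL,
                      passengerLesionsPerSample = 10, lesionSizeMean = 50,
                      amplitudeWeights = c(0.7, 0.3),
                      passengerMutationRate = 0.002,
                      driverMutationRate = 0.15,
                      ploidy = 2, geneLength = 10000, geneSpacing = 100000,
                      seed = 20130325) {
    stopifnot(nGenes >= nChromosomes, nChromosomes >= 1, nSamples >= 1,
              passengerLesionsPerSample >= 0, lesionSizeMean >= 1,
              length(amplitudeWeights) == 2, all(amplitudeWeights >= 0),
              passengerMutationRate >= 0, passengerMutationRate <= 1,
              driverMutationRate >= 0, driverMutationRate <= 1,
              ploidy >= 1, geneLength < geneSpacing)
    symbols <- sprintf("G%05d", seq_len(nGenes))
    if (is.null(drivers)) {
        idx <- floor(nGenes * (2 * seq_len(5) - 1) / 10)
        drivers <- data.frame(
            symbol = symbols[idx],
            type = c("gain", "deletion", "gain", "deletion", "gain"),
            hitProb = 0.4, focalSizeMean = 3,
            stringsAsFactors = FALSE)
    }
    stopifnot(all(drivers$symbol %in% symbols),
              all(drivers$type %in% c("gain", "deletion")),
              all(drivers$hitProb >= 0 & drivers$hitProb <= 1),
              all(drivers$focalSizeMean >= 1))
    structure(list(
        nGenes = nGenes, nChromosomes = nChromosomes, nSamples = nSamples,
        drivers = drivers,
        passengerLesionsPerSample = passengerLesionsPerSample,
        lesionSizeMean = lesionSizeMean,
        amplitudeWeights = amplitudeWeights / sum(amplitudeWeights),
        passengerMutationRate = passengerMutationRate,
        driverMutationRate = driverMutationRate,
        ploidy = ploidy, geneLength = geneLength, geneSpacing = geneSpacing,
        seed = seed), class = "SimConfig")
}

## geometric size with the stated mean (>= 1 genes)
rGeomSize <- function(mean) {
    if (mean <= 1) return(1L)
    1L + rgeom(1L, prob = 1 / mean)
}

## merge possibly-overlapping index intervals of one sample/type into
## disjoint lesions (union of indices, max amplitude) -- the generator's
## own merge, kept independent of the interval-overlap machinery
mergeIndexLesions <- function(tab, symbols) {
    if (nrow(tab) == 0L) return(list())
    tab <- tab[order(tab$from, tab$to), , drop = FALSE]
    out <- list()
    curFrom <- tab$from[1]; curTo <- tab$to[1]; curAmp <- tab$amp[1]
    flush <- function() {
        out[[length(out) + 1L]] <<- list(
            amplitude = curAmp, genes = symbols[curFrom:curTo])
    }
    for (i in seq_len(nrow(tab))[-1]) {
        if (tab$from[i] <= curTo) {
            curTo <- max(curTo, tab$to[i])
            curAmp <- max(curAmp, tab$amp[i])
        } else {
            flush()
            curFrom <- tab$from[i]; curTo <- tab$to[i]; curAmp <- tab$amp[i]
        }
    }
    flush()
    out
}

#' Simulate a synthetic tumor cohort with implanted drivers
#'
#' Draws a cohort from the generative model described in [simConfig()].
#' The outputs serialize (via [writeCohort()]) to valid inputs for
#' [readGeneModel()], [readSeg()] and [readMutations()], which is how the
#' package's end-to-end tests exercise the full pipeline without external
#' data.
#'
#' @param config A \code{SimConfig}.
#' @return A list with components \code{model}
#'   (\linkS4class{GeneModel}), \code{segments} (data.frame as returned
#'   by [readSeg()]), \code{mutations} (data.frame as returned by
#'   [readMutations()]), \code{truth} (the driver table), and
#'   \code{lesionSets} (the generator's own per-sample gain/deletion
#'   \linkS4class{LesionSet}s, for round-trip checks).
#' @export
simulateCohort <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    if (exists(".Random.seed", envir = globalenv())) {
        oldSeed <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
    }
    set.seed(config$seed)
    nG <- config$nGenes
    nC <- config$nChromosomes
    symbols <- sprintf("G%05d", seq_len(nG))
    perChrom <- ceiling(nG / nC)
    chromOf <- (seq_len(nG) - 1L) %/% perChrom + 1L
    posInChrom <- (seq_len(nG) - 1L) %% perChrom
    geneStart <- posInChrom * config$geneSpacing
    geneEnd <- geneStart + config$geneLength
    chromFirst <- vapply(seq_len(nC), function(c) min(which(chromOf == c)),
                         integer(1))
    chromLast <- vapply(seq_len(nC), function(c) max(which(chromOf == c)),
                        integer(1))
    geneTable <- data.frame(symbol = symbols,
                            chromosome = paste0("chr", chromOf),
                            start = geneStart, end = geneEnd,
                            stringsAsFactors = FALSE)
    model <- geneModelFromTable(geneTable)

    drivers <- config$drivers
    driverIdx <- match(drivers$symbol, symbols)
    samples <- sprintf("S%03d", seq_len(config$nSamples))
    lesionRows <- list()
    mutRows <- list()
    for (s in samples) {
        ## passenger copy-number lesions
        nPass <- rpois(1L, config$passengerLesionsPerSample)
        for (k in seq_len(nPass)) {
            chrom <- sample.int(nC, 1L)
            lo <- chromFirst[chrom]; hi <- chromLast[chrom]
            from <- lo + sample.int(hi - lo + 1L, 1L) - 1L
            size <- rGeomSize(config$lesionSizeMean)
            to <- min(hi, from + size - 1L)
            type <- sample(c("gain", "deletion"), 1L)
            amp <- sample(1:2, 1L, prob = config$amplitudeWeights)
            lesionRows[[length(lesionRows) + 1L]] <- data.frame(
                sample = s, type = type, amp = amp, from = from, to = to,
                stringsAsFactors = FALSE)
        }
        ## focal driver lesions
        for (d in seq_len(nrow(drivers))) {
            if (runif(1L) >= drivers$hitProb[d])
                next
            di <- driverIdx[d]
            chrom <- chromOf[di]
            size <- rGeomSize(drivers$focalSizeMean[d])
            offset <- sample.int(size, 1L) - 1L
            from <- max(chromFirst[chrom], di - offset)
            to <- min(chromLast[chrom], from + size - 1L)
            to <- max(to, di)
            amp <- sample(1:2, 1L, prob = config$amplitudeWeights)
            lesionRows[[length(lesionRows) + 1L]] <- data.frame(
                sample = s, type = drivers$type[d], amp = amp,
                from = from, to = to, stringsAsFactors = FALSE)
        }
        ## point mutations: genome-wide passenger noise + driver excess
        hit <- which(runif(nG) < config$passengerMutationRate)
        driverHit <- driverIdx[runif(nrow(drivers)) <
                               config$driverMutationRate]
        hit <- sort(unique(c(hit, driverHit)))
        if (length(hit))
            mutRows[[length(mutRows) + 1L]] <- data.frame(
                sample = s, gene = symbols[hit], stringsAsFactors = FALSE)
    }
    lesionTab <- if (length(lesionRows)) do.call(rbind, lesionRows)
                 else data.frame(sample = character(), type = character(),
                                 amp = numeric(), from = integer(),
                                 to = integer(), stringsAsFactors = FALSE)
    ## serialize lesions as segments (internal 0-based half-open)
    segments <- data.frame(
        sample = lesionTab$sample,
        chromosome = paste0("chr", chromOf[lesionTab$from]),
        start = geneStart[lesionTab$from],
        end = geneEnd[lesionTab$to],
        cn = ifelse(lesionTab$type == "gain",
                    config$ploidy + lesionTab$amp,
                    pmax(0, config$ploidy - lesionTab$amp)),
        stringsAsFactors = FALSE)
    ## the generator's own lesion sets (index-space merge)
    lesionSets <- list()
    for (s in unique(lesionTab$sample)) {
        sub <- lesionTab[lesionTab$sample == s, , drop = FALSE]
        lesionSets[[s]] <- list(
            gain = LesionSet(s, "gain", mergeIndexLesions(
                sub[sub$type == "gain", , drop = FALSE], symbols)),
            deletion = LesionSet(s, "deletion", mergeIndexLesions(
                sub[sub$type == "deletion", , drop = FALSE], symbols)))
    }
    mutations <- if (length(mutRows)) do.call(rbind, mutRows)
                 else data.frame(sample = character(), gene = character(),
                                 stringsAsFactors = FALSE)
    mutations$classification <- rep(NA_character_, nrow(mutations))
    rownames(segments) <- rownames(mutations) <- NULL
    list(model = model, segments = segments, mutations = mutations,
         truth = drivers, lesionSets = lesionSets)
}

#' Write a simulated cohort to disk
#'
#' Serializes a cohort from [simulateCohort()] into the external formats
#' the readers accept: \code{genes.bed} (0-based half-open BED),
#' \code{cohort.seg} (1-based inclusive SEG with header),
#' \code{mutations.tsv} (minimal sample/gene TSV) and \code{truth.txt}
#' (driver symbol and type per line).
#'
#' @param cohort A list from [simulateCohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths of the four files written.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    gr <- geneRanges(cohort$model)
    bed <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1,
                      end = GenomicRanges::end(gr),
                      name = gr$symbol, stringsAsFactors = FALSE)
    paths <- c(genes = file.path(dir, "genes.bed"),
               seg = file.path(dir, "cohort.seg"),
               mutations = file.path(dir, "mutations.tsv"),
               truth = file.path(dir, "truth.txt"))
    write.table(bed, paths["genes"], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    seg <- data.frame(sample = cohort$segments$sample,
                      chromosome = cohort$segments$chromosome,
                      start = cohort$segments$start + 1,
                      end = cohort$segments$end,
                      value = cohort$segments$cn, stringsAsFactors = FALSE)
    write.table(seg, paths["seg"], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
    write.table(cohort$mutations[c("sample", "gene")], paths["mutations"],
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
    write.table(cohort$truth[c("symbol", "type")], paths["truth"],
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(paths)
}

#' Driver-recovery report
#'
#' Ranks the gene universe by score (descending, ties broken by genome
#' order) and reports how many of the true driver genes appear in the top
#' \code{k} and their mean rank.  A truth gene absent from the score
#' vector gets rank \code{|universe| + 1} by convention.
#'
#' @param truth Character vector of true driver symbols.
#' @param scores A \linkS4class{ScoreVector}.
#' @param k Size of the top list (default 10).
#' @return A list with \code{hitsInTopK}, \code{meanRank} and the named
#'   \code{ranks} of the truth genes.
#' @export
recoveryReport <- function(truth, scores, k = 10) {
    if (length(truth) == 0L)
        stop("empty truth set", call. = FALSE)
    v <- scoreValues(scores)
    ranking <- names(v)[order(-v, seq_along(v))]
    ranks <- match(truth, ranking)
    ranks[is.na(ranks)] <- length(v) + 1L
    names(ranks) <- truth
    list(hitsInTopK = sum(ranks <= k), meanRank = mean(ranks),
         ranks = ranks)
}
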