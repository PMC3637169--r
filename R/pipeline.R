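## score one family (a list of LesionSets of one type) according to the
## configured mode; returns list(score=ScoreVector, trace=PriorTrace|NULL)
scoreFamily <- function(samples, model, posterior, scoreMode, priorMode,
                        tol, maxIter) {
    samples <- Filter(function(s) length(lesionList(s)) > 0, samples)
    if (length(samples) == 0L)
        return(NULL)
    if (scoreMode == "heuristic") {
        measure <- if (posterior == "recurrence") "recurrence" else "focality"
        return(list(score = heuristicScores(samples, model, measure),
                    trace = NULL))
    }
    if (priorMode == "single_pass") {
        postFn <- if (posterior == "recurrence") recurrencePosterior
                  else focalityPosterior
        prior <- uniformPrior(model)
        score <- aggregatePosteriors(lapply(samples, postFn, prior = prior))
        return(list(score = score, trace = NULL))
    }
    trace <- iterateEmpiricalPrior(samples, model, posterior = posterior,
                                   tol = tol, maxIter = maxIter,
                                   keepIterates = FALSE)
    list(score = finalPrior(trace), trace = trace)
}

traceSummary <- function(trace, tol, mode) {
    if (is.null(trace))
        return(list(n_iter = 1, converged = NA, final_kl = NA, tol = tol,
                    mode = mode))
    kl <- klSteps(trace)
    list(n_iter = nIterations(trace), converged = isConverged(trace),
         final_kl = kl[length(kl)], tol = tol, mode = mode)
}

#' Run the full driver-prioritization pipeline
#'
#' Orchestrates the analysis end to end: copy-number lesion sets are
#' scored for recurrence and focality (separately for gains and
#' deletions), the two are combined multiplicatively, recurrently mutated
#' genes produce a mutation score, mutation and copy-number evidence are
#' integrated, and every resulting distribution is discretized into
#' entropy tiers and grouped into leader-labeled genomic regions.  Each
#' analysis is produced only when its inputs exist.
#'
#' @param model A \linkS4class{GeneModel}.
#' @param segments Optional segment data.frame from [readSeg()].
#' @param mutations Optional mutation records from [readMutations()].
#' @param scoreMode \code{"bayes"} (posterior scores; default) or
#'   \code{"heuristic"} (additive D/L and D/T compatibility mode).
#' @param priorMode \code{"fixed_point"} (iterate the empirical prior to
#'   convergence; default) or \code{"single_pass"} (one aggregation under
#'   the uniform prior).
#' @param tol,maxIter Stopping tolerance (bits) and iteration cap for the
#'   empirical-prior iteration.
#' @param ploidy Baseline copy number (default 2).
#' @param minMutSamples Recurrence threshold for mutations (default 2).
#' @param mutationMode \code{"binary"} or \code{"count"} lesion
#'   amplitudes for mutations.
#' @param maxTier,gapGenes,topK Region-construction parameters, see
#'   [buildRegions()].
#' @return A \code{FocalResults} list with components \code{scores} (named
#'   list of \linkS4class{ScoreVector}s: \code{gain_recurrence},
#'   \code{gain_focality}, \code{gain} (combined), likewise for
#'   \code{deletion}, \code{mutation}, \code{integrated_gain},
#'   \code{integrated_deletion}), \code{tiers} and \code{regions} (named
#'   lists of tables for the headline analyses), and \code{metadata}.
#' @export
runPipeline <- function(model, segments = NULL, mutations = NULL,
                        scoreMode = c("bayes", "heuristic"),
                        priorMode = c("fixed_point", "single_pass"),
                        tol = 1e-6, maxIter = 100, ploidy = 2,
                        minMutSamples = 2,
                        mutationMode = c("binary", "count"),
                        maxTier = 1, gapGenes = 10, topK = 25) {
    scoreMode <- match.arg(scoreMode)
    priorMode <- match.arg(priorMode)
    mutationMode <- match.arg(mutationMode)
    stopifnot(is(model, "GeneModel"))
    if (is.null(segments) && is.null(mutations))
        stop("at least one of segments or mutations is required",
             call. = FALSE)
    scores <- list()
    traces <- list()
    if (!is.null(segments)) {
        sets <- buildLesionSets(segments, model, ploidy = ploidy)
        for (type in c("gain", "deletion")) {
            fam <- lapply(sets, `[[`, type)
            rec <- scoreFamily(fam, model, "recurrence", scoreMode,
                               priorMode, tol, maxIter)
            foc <- scoreFamily(fam, model, "focality", scoreMode,
                               priorMode, tol, maxIter)
            if (is.null(rec) || is.null(foc)) {
                warning("no ", type, " lesions in any sample; skipping ",
                        type, " analyses", call. = FALSE)
                next
            }
            scores[[paste0(type, "_recurrence")]] <- rec$score
            scores[[paste0(type, "_focality")]] <- foc$score
            scores[[type]] <- combineScores(foc$score, rec$score)
            traces[[paste0(type, "_recurrence")]] <-
                traceSummary(rec$trace, tol, priorMode)
            traces[[paste0(type, "_focality")]] <-
                traceSummary(foc$trace, tol, priorMode)
        }
    }
    if (!is.null(mutations)) {
        recurrent <- filterRecurrent(mutations, minSamples = minMutSamples)
        mutSets <- mutationLesionSets(recurrent, mode = mutationMode)
        if (length(mutSets) == 0L) {
            warning("no recurrently mutated genes; skipping mutation ",
                    "analyses", call. = FALSE)
        } else {
            res <- scoreFamily(mutSets, model, "recurrence", scoreMode,
                               priorMode, tol, maxIter)
            scores[["mutation"]] <- res$score
            traces[["mutation"]] <- traceSummary(res$trace, tol, priorMode)
            for (type in c("gain", "deletion")) {
                rec <- scores[[paste0(type, "_recurrence")]]
                foc <- scores[[paste0(type, "_focality")]]
                if (is.null(rec) || is.null(foc))
                    next
                scores[[paste0("integrated_", type)]] <-
                    tryCatch(integrateMutCn(scores[["mutation"]], rec, foc),
                             error = function(e) {
                                 warning("integrated ", type, " score: ",
                                         conditionMessage(e), call. = FALSE)
                                 NULL
                             })
            }
        }
    }
    if (length(scores) == 0L)
        stop("no analysis could be produced from the given inputs",
             call. = FALSE)
    ## tiers and regions for each headline analysis
    headline <- intersect(c("gain", "deletion", "mutation",
                            "integrated_gain", "integrated_deletion"),
                          names(scores))
    tiers <- list()
    regions <- list()
    for (a in headline) {
        tiers[[a]] <- assignTiers(scores[[a]])
        regions[[a]] <- buildRegions(scores[[a]], tiers[[a]], model,
                                     maxTier = maxTier,
                                     gapGenes = gapGenes, topK = topK)
    }
    metadata <- list(
        package = "focalDrivers",
        version = as.character(packageVersion("focalDrivers")),
        config = list(score_mode = scoreMode, prior_mode = priorMode,
                      tol = tol, max_iter = maxIter, ploidy = ploidy,
                      min_mut_samples = minMutSamples,
                      mutation_mode = mutationMode, max_tier = maxTier,
                      gap_genes = gapGenes, top_k = topK),
        n_genes = nGenes(model),
        iteration = traces)
    structure(list(scores = scores, tiers = tiers, regions = regions,
                   metadata = metadata), class = "FocalResults")
}

scoreTable <- function(results, analysis, model) {
    scores <- results$scores
    main <- scoreValues(scores[[analysis]])
    keep <- main > 0
    gr <- geneRanges(model)
    idx <- match(names(main)[keep], gr$symbol)
    tab <- data.frame(
        gene = names(main)[keep],
        chromosome = as.character(GenomicRanges::seqnames(gr))[idx],
        start = GenomicRanges::start(gr)[idx] - 1,
        end = GenomicRanges::end(gr)[idx],
        stringsAsFactors = FALSE)
    if (analysis %in% c("gain", "deletion")) {
        tab$recurrence <-
            scoreValues(scores[[paste0(analysis, "_recurrence")]])[keep]
        tab$focality <-
            scoreValues(scores[[paste0(analysis, "_focality")]])[keep]
        tab$combined <- main[keep]
    } else {
        tab$score <- main[keep]
    }
    tab <- tab[order(idx), , drop = FALSE]
    rownames(tab) <- NULL
    tab
}

#' Write pipeline results to an output directory
#'
#' Writes, per analysis, \code{{analysis}.scores.tsv} (genome order, only
#' genes with positive score), \code{{analysis}.tiers.tsv},
#' \code{{analysis}.regions.tsv} and \code{{analysis}.regions.json}, plus
#' a \code{run_metadata.json} recording the resolved configuration and
#' the empirical-prior iteration traces.  Identical inputs and
#' configuration produce byte-identical files.
#'
#' @param results A \code{FocalResults} from [runPipeline()].
#' @param model The \linkS4class{GeneModel} the results were computed on.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeResults <- function(results, model, dir) {
    stopifnot(inherits(results, "FocalResults"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character()
    writeTsv <- function(tab, path) {
        write.table(tab, path, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = TRUE)
        paths <<- c(paths, path)
    }
    for (a in names(results$tiers)) {
        writeTsv(scoreTable(results, a, model),
                 file.path(dir, paste0(a, ".scores.tsv")))
        writeTsv(results$tiers[[a]],
                 file.path(dir, paste0(a, ".tiers.tsv")))
        writeTsv(results$regions[[a]],
                 file.path(dir, paste0(a, ".regions.tsv")))
        jsonPath <- file.path(dir, paste0(a, ".regions.json"))
        jsonlite::write_json(results$regions[[a]], jsonPath,
                             dataframe = "rows", auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
        paths <- c(paths, jsonPath)
    }
    metaPath <- file.path(dir, "run_metadata.json")
    jsonlite::write_json(results$metadata, metaPath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null",
                         na = "null")
    paths <- c(paths, metaPath)
    invisible(paths)
}
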