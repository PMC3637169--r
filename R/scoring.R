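## Prior mass of each lesion's gene set under a prior value vector.
lesionPriorMass <- function(lesions, priorValues) {
    vapply(lesions, function(l) sum(priorValues[l$genes]), numeric(1))
}

emptyScore <- function(universe, role) {
    ScoreVector(setNames(numeric(length(universe)), universe), role = role)
}

normalizeScore <- function(values, role) {
    s <- sum(values)
    if (s > 0) values <- values / s
    ScoreVector(values, role = role)
}

#' Uniform prior over the gene universe
#'
#' @param model A \linkS4class{GeneModel}.
#' @return A \linkS4class{ScoreVector} with equal mass on every gene.
#' @export
uniformPrior <- function(model) {
    g <- geneSymbols(model)
    ScoreVector(setNames(rep(1 / length(g), length(g)), g), role = "prior")
}

#' Per-sample recurrence posterior
#'
#' The recurrence score of a sample is the global posterior probability
#' that a gene drives the phenotype given that all altered genes are
#' candidates: for lesions \eqn{(C_i, N_i)} and prior \eqn{P^d},
#' \deqn{R(D|S) = \frac{\sum_i C_i\,\delta(D \in N_i)\,P^d(D)}
#'                     {\sum_i C_i \sum_{G \in N_i} P^d(G)}.}
#' With a uniform prior and unit amplitudes every altered gene gets
#' \eqn{1/K} (\eqn{K} = number of altered genes); with amplitudes, a gene
#' in a lesion of amplitude \eqn{C} gets \eqn{C/T} where \eqn{T} is the
#' amplitude-weighted count of altered genes.
#'
#' Lesions none of whose genes carries prior mass contribute nothing; if no
#' lesion carries prior mass the all-zero "empty" vector is returned (and
#' is excluded from aggregation downstream).
#'
#' @param sample A \linkS4class{LesionSet}.
#' @param prior A normalized \linkS4class{ScoreVector} over the universe.
#' @return A \linkS4class{ScoreVector} with role
#'   \code{"per_sample_posterior"}.
#' @seealso [focalityPosterior()], [aggregatePosteriors()]
#' @export
recurrencePosterior <- function(sample, prior) {
    stopifnot(is(sample, "LesionSet"), is(prior, "ScoreVector"))
    pv <- scoreValues(prior)
    lesions <- lesionList(sample)
    v <- setNames(numeric(length(pv)), names(pv))
    if (length(lesions) == 0L)
        return(ScoreVector(v, role = "per_sample_posterior"))
    mass <- lesionPriorMass(lesions, pv)
    amp <- vapply(lesions, `[[`, numeric(1), "amplitude")
    denom <- sum(amp * mass)
    if (denom == 0)
        return(ScoreVector(v, role = "per_sample_posterior"))
    for (i in seq_along(lesions)) {
        g <- lesions[[i]]$genes
        v[g] <- v[g] + amp[i] * pv[g]
    }
    normalizeScore(v, role = "per_sample_posterior")
}

#' Per-sample focality posterior
#'
#' The focality score of a sample is the local posterior in which every
#' lesion is first given an (amplitude-weighted) equal chance of containing
#' the driver, and the chosen lesion's prior mass is then shared among its
#' own genes:
#' \deqn{F(D|S) = \sum_i \frac{C_i}{\sum_j C_j}\,
#'       \frac{\delta(D \in N_i)\,P^d(D)}{\sum_{G \in N_i} P^d(G)}.}
#' With a uniform prior and unit amplitudes a gene in a lesion of \eqn{L}
#' genes among \eqn{t} lesions gets \eqn{1/(tL)}: genes in smaller
#' (more focal) lesions score higher.
#'
#' Lesions with zero prior mass are excluded (the output is renormalized
#' over the remaining lesions); if none carries prior mass the all-zero
#' "empty" vector is returned.
#'
#' @inheritParams recurrencePosterior
#' @return A \linkS4class{ScoreVector} with role
#'   \code{"per_sample_posterior"}.
#' @export
focalityPosterior <- function(sample, prior) {
    stopifnot(is(sample, "LesionSet"), is(prior, "ScoreVector"))
    pv <- scoreValues(prior)
    lesions <- lesionList(sample)
    v <- setNames(numeric(length(pv)), names(pv))
    if (length(lesions) == 0L)
        return(ScoreVector(v, role = "per_sample_posterior"))
    mass <- lesionPriorMass(lesions, pv)
    amp <- vapply(lesions, `[[`, numeric(1), "amplitude")
    usable <- mass > 0
    if (!any(usable))
        return(ScoreVector(v, role = "per_sample_posterior"))
    ampSum <- sum(amp[usable])
    for (i in which(usable)) {
        g <- lesions[[i]]$genes
        v[g] <- v[g] + (amp[i] / ampSum) * pv[g] / mass[i]
    }
    normalizeScore(v, role = "per_sample_posterior")
}

#' Aggregate per-sample posteriors across a cohort
#'
#' The cohort-level score is the arithmetic mean of the per-sample
#' posterior distributions (equivalently: summed across samples and
#' normalized).  All-zero "empty" vectors from unscorable samples are
#' excluded.
#'
#' @param perSample List of \linkS4class{ScoreVector}s over one universe.
#' @return A \linkS4class{ScoreVector} with role \code{"aggregated"}.
#' @export
aggregatePosteriors <- function(perSample) {
    usable <- Filter(function(p) !isEmptyScore(p), perSample)
    if (length(usable) == 0L)
        stop("no scorable samples", call. = FALSE)
    mats <- vapply(usable, scoreValues,
                   numeric(length(scoreValues(usable[[1]]))))
    v <- rowMeans(mats)
    names(v) <- names(scoreValues(usable[[1]]))
    normalizeScore(v, role = "aggregated")
}

#' Combine focality and recurrence scores
#'
#' The combined score is the gene-wise product of the two distributions,
#' renormalized.  Its support is the intersection of the two supports.
#'
#' @param focality,recurrence Normalized \linkS4class{ScoreVector}s over
#'   the same universe.
#' @return A \linkS4class{ScoreVector} with role \code{"combined"}.
#' @export
combineScores <- function(focality, recurrence) {
    f <- scoreValues(focality)
    r <- scoreValues(recurrence)
    stopifnot(identical(names(f), names(r)))
    v <- f * r
    if (sum(v) == 0)
        stop("disjoint supports", call. = FALSE)
    normalizeScore(v, role = "combined")
}

#' Cohort mutation score
#'
#' In a sample with \eqn{N} mutated genes each mutated gene gets a sample
#' score of \eqn{1/N} (uniform prior), and sample scores are averaged
#' across the cohort.  Because every mutation lesion covers exactly one
#' gene, the recurrence and focality posteriors coincide, so a single
#' vector is returned.
#'
#' @param samples Named list of mutation \linkS4class{LesionSet}s.
#' @param prior Normalized \linkS4class{ScoreVector}.
#' @return A \linkS4class{ScoreVector} with role \code{"aggregated"}.
#' @export
mutationScores <- function(samples, prior) {
    if (length(samples) == 0L)
        stop("no scorable samples", call. = FALSE)
    aggregatePosteriors(lapply(samples, recurrencePosterior, prior = prior))
}

#' Integrate mutation and copy-number scores
#'
#' For each gene the integrated (gain/mutation or deletion/mutation) score
#' is the product of its mutation score and the sum of its copy-number
#' recurrence and focality scores, renormalized.  Genes with zero mutation
#' score get zero integrated score.
#'
#' @param mutation Cohort mutation \linkS4class{ScoreVector}.
#' @param cnRecurrence,cnFocality Cohort copy-number recurrence and
#'   focality \linkS4class{ScoreVector}s of one alteration type.
#' @return A \linkS4class{ScoreVector} with role \code{"integrated"}.
#' @export
integrateMutCn <- function(mutation, cnRecurrence, cnFocality) {
    m <- scoreValues(mutation)
    r <- scoreValues(cnRecurrence)
    f <- scoreValues(cnFocality)
    stopifnot(identical(names(m), names(r)), identical(names(m), names(f)))
    v <- m * (r + f)
    if (sum(v) == 0)
        stop("empty product support", call. = FALSE)
    normalizeScore(v, role = "integrated")
}

#' Heuristic cohort scores (compatibility mode)
#'
#' A simpler additive variant of the scores: per sample each altered gene
#' gets \eqn{D/L} (focality) or \eqn{D/T} (recurrence), where \eqn{D} is
#' the amplitude of its lesion, \eqn{L} the lesion's gene count and
#' \eqn{T} the amplitude-weighted count of altered genes; the per-gene
#' values are summed across samples and normalized once at the end, rather
#' than sample by sample.  The Bayesian posteriors (the default mode)
#' differ only by that per-sample normalization.
#'
#' @param samples Named list of \linkS4class{LesionSet}s of one type.
#' @param model A \linkS4class{GeneModel}.
#' @param measure \code{"focality"} or \code{"recurrence"}.
#' @return A \linkS4class{ScoreVector} with role \code{"aggregated"}.
#' @export
heuristicScores <- function(samples, model,
                            measure = c("focality", "recurrence")) {
    measure <- match.arg(measure)
    g <- geneSymbols(model)
    v <- setNames(numeric(length(g)), g)
    any <- FALSE
    for (ls in samples) {
        lesions <- lesionList(ls)
        if (length(lesions) == 0L)
            next
        amp <- vapply(lesions, `[[`, numeric(1), "amplitude")
        len <- vapply(lesions, function(l) length(l$genes), numeric(1))
        total <- sum(amp * len)
        for (i in seq_along(lesions)) {
            genes <- lesions[[i]]$genes
            v[genes] <- v[genes] +
                if (measure == "focality") amp[i] / len[i] else amp[i] / total
        }
        any <- TRUE
    }
    if (!any)
        stop("no scorable samples", call. = FALSE)
    normalizeScore(v, role = "aggregated")
}
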