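#' Kullback-Leibler divergence between score vectors
#'
#' \eqn{KL(p \| q) = \sum_g p(g) \log_2(p(g)/q(g))} in bits, with
#' \eqn{0 \log 0 := 0}.  Requires \eqn{p}'s support to be contained in
#' \eqn{q}'s; the empirical-prior update guarantees this by construction
#' (posterior mass requires prior mass).
#'
#' @param p,q \linkS4class{ScoreVector}s (or named numeric distributions)
#'   over the same universe.
#' @return Non-negative divergence in bits; 0 iff \code{p == q}.
#' @export
klDivergence <- function(p, q) {
    pv <- if (is(p, "ScoreVector")) scoreValues(p) else p
    qv <- if (is(q, "ScoreVector")) scoreValues(q) else q
    stopifnot(length(pv) == length(qv))
    pos <- pv > 0
    if (any(pos & qv == 0))
        stop("support of p not contained in support of q", call. = FALSE)
    sum(pv[pos] * log2(pv[pos] / qv[pos]))
}

## Flat index representation of a cohort's lesion sets for fast repeated
## posterior updates: one row per (lesion, gene) membership.
indexCohort <- function(samples, universe) {
    geneIdx <- integer(0)
    lesionId <- integer(0)
    lesionSample <- integer(0)
    lesionAmp <- numeric(0)
    L <- 0L
    for (s in seq_along(samples)) {
        for (les in lesionList(samples[[s]])) {
            L <- L + 1L
            idx <- match(les$genes, universe)
            geneIdx <- c(geneIdx, idx)
            lesionId <- c(lesionId, rep(L, length(idx)))
            lesionSample <- c(lesionSample, s)
            lesionAmp <- c(lesionAmp, les$amplitude)
        }
    }
    list(geneIdx = geneIdx, lesionId = lesionId,
         lesionSample = lesionSample, lesionAmp = lesionAmp,
         nSamples = length(samples), nLesions = L)
}

## One empirical-prior update (mean of per-sample posteriors) on the flat
## representation; algebraically identical to aggregatePosteriors() over
## recurrencePosterior()/focalityPosterior(), but vectorized.
batchUpdate <- function(ix, p, posterior) {
    entryP <- p[ix$geneIdx]
    rs <- rowsum(entryP, ix$lesionId)
    mass <- numeric(ix$nLesions)
    mass[as.integer(rownames(rs))] <- rs[, 1]
    if (posterior == "recurrence") {
        wLesion <- ix$lesionAmp * mass
        denom <- numeric(ix$nSamples)
        rs <- rowsum(wLesion, ix$lesionSample)
        denom[as.integer(rownames(rs))] <- rs[, 1]
        usable <- denom > 0
        denomSafe <- ifelse(usable, denom, 1)
        entryW <- ix$lesionAmp[ix$lesionId] * entryP /
            denomSafe[ix$lesionSample[ix$lesionId]]
    } else {
        liveAmp <- ix$lesionAmp * (mass > 0)
        ampSum <- numeric(ix$nSamples)
        rs <- rowsum(liveAmp, ix$lesionSample)
        ampSum[as.integer(rownames(rs))] <- rs[, 1]
        usable <- ampSum > 0
        ampSafe <- ifelse(usable, ampSum, 1)
        massSafe <- ifelse(mass > 0, mass, 1)
        entryW <- (liveAmp[ix$lesionId] /
                   ampSafe[ix$lesionSample[ix$lesionId]]) *
            entryP / massSafe[ix$lesionId]
    }
    nUsable <- sum(usable)
    if (nUsable == 0L)
        stop("no scorable samples", call. = FALSE)
    out <- numeric(length(p))
    rs <- rowsum(entryW, ix$geneIdx)
    out[as.integer(rownames(rs))] <- rs[, 1]
    out <- out / nUsable
    out / sum(out)
}

#' Iterate the empirical prior to its fixed point
#'
#' Starting from the uniform prior \eqn{P_0} over the gene universe, each
#' update replaces the prior by the cohort mean of the per-sample
#' posteriors computed under it:
#' \deqn{P_{j+1}(D) = \frac{1}{T} \sum_{i=1}^{T} P_j(D \mid S_i),}
#' and stops as soon as the Kullback-Leibler divergence between
#' consecutive iterates falls below \code{tol} (in bits), or after
#' \code{maxIter} updates with a warning.  The first update equals the
#' single-pass aggregated score; further updates sharpen the distribution
#' toward genes that explain the cohort ("rich-get-richer"), which is why
#' the iteration count is capped and reported.
#'
#' Samples whose lesions carry no mass under the current prior are
#' excluded from that update (their posterior is the empty vector).
#'
#' @param samples List of \linkS4class{LesionSet}s, one per sample.
#' @param model A \linkS4class{GeneModel} defining the universe.
#' @param posterior Which posterior family to iterate:
#'   \code{"recurrence"} or \code{"focality"}.
#' @param tol Stopping tolerance in bits (default 1e-6).
#' @param maxIter Maximum number of updates (default 100).
#' @param keepIterates Keep every iterate in the trace (default TRUE);
#'   otherwise only \eqn{P_0} and the final iterate are retained.
#' @return A \linkS4class{PriorTrace}; [finalPrior()] extracts the fixed
#'   point.
#' @export
iterateEmpiricalPrior <- function(samples, model,
                                  posterior = c("recurrence", "focality"),
                                  tol = 1e-6, maxIter = 100,
                                  keepIterates = TRUE) {
    posterior <- match.arg(posterior)
    stopifnot(tol > 0, maxIter >= 1)
    samples <- Filter(function(s) length(lesionList(s)) > 0, samples)
    if (length(samples) == 0L)
        stop("no scorable samples", call. = FALSE)
    universe <- geneSymbols(model)
    ix <- indexCohort(samples, universe)
    p <- uniformPrior(model)
    pv <- scoreValues(p)
    iterates <- list(p)
    kl <- numeric()
    converged <- FALSE
    for (j in seq_len(maxIter)) {
        vNew <- batchUpdate(ix, pv, posterior)
        if (any(!is.finite(vNew)))
            stop("non-finite values at iteration ", j, call. = FALSE)
        names(vNew) <- universe
        step <- klDivergence(vNew, pv)
        kl <- c(kl, step)
        if (keepIterates)
            iterates[[length(iterates) + 1L]] <- ScoreVector(vNew,
                                                             role = "prior")
        pv <- vNew
        if (step < tol) {
            converged <- TRUE
            break
        }
    }
    p <- ScoreVector(pv, role = "prior")
    if (!converged) {
        warning("empirical-prior iteration did not converge in ", maxIter,
                " updates (last KL step ", format(kl[length(kl)],
                digits = 4), " bits)", call. = FALSE)
    }
    if (!keepIterates)
        iterates[[2L]] <- p
    new("PriorTrace", iterates = iterates, kl = kl,
        converged = converged, tol = tol)
}
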