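#' Shannon entropy of a score distribution
#'
#' \eqn{H(P) = -\sum_g P(g) \log_2 P(g)} in bits, with
#' \eqn{0 \log 0 := 0}.  Zero iff the distribution is a point mass;
#' \eqn{\log_2 N} iff uniform over \eqn{N} genes.  A distribution with
#' entropy \eqn{h} behaves like one uniform on \eqn{2^h} genes, which is
#' what the tier threshold exploits.
#'
#' @param p A normalized \linkS4class{ScoreVector} or named numeric
#'   distribution.
#' @return Entropy in bits.
#' @export
scoreEntropy <- function(p) {
    v <- if (is(p, "ScoreVector")) scoreValues(p) else p
    v <- v[v > 0]
    -sum(v * log2(v))
}

#' Assign entropy-defined tiers
#'
#' Discretizes a score distribution into confidence tiers.  Round \eqn{k}
#' declares every gene with renormalized probability strictly above
#' \eqn{2^{-H(P_k)}} to be in tier \eqn{k}, removes those genes,
#' renormalizes, and repeats until no genes remain.  When a round assigns
#' no gene (the remaining distribution is uniform, or a single gene
#' remains, so no value strictly exceeds the threshold), all remaining
#' genes form one final remainder tier.  Zero-score genes are left
#' untiered.
#'
#' @param p A normalized \linkS4class{ScoreVector}.
#' @return A data.frame with columns \code{gene}, \code{score},
#'   \code{tier}, ordered by decreasing score within increasing tier, with
#'   attributes \code{thresholds} (the \eqn{2^{-H}} value of each round)
#'   and \code{remainder} (whether the last tier is a remainder tier).
#' @export
assignTiers <- function(p) {
    v <- scoreValues(p)
    v <- v[v > 0]
    tiers <- integer(0)
    genes <- character(0)
    thresholds <- numeric(0)
    remainder <- FALSE
    cur <- v / sum(v)
    k <- 0L
    while (length(cur) > 0L) {
        k <- k + 1L
        thr <- 2^(-scoreEntropy(cur))
        thresholds <- c(thresholds, thr)
        ## strict exceedance; the relative slack keeps exact ties (an
        ## exactly uniform remainder, where 2^-H equals every value up to
        ## rounding) on the non-exceeding side
        sel <- cur > thr * (1 + 1e-9)
        if (!any(sel)) {
            ## degenerate round: park everything left in one remainder tier
            sel <- rep(TRUE, length(cur))
            remainder <- TRUE
        }
        genes <- c(genes, names(cur)[sel])
        tiers <- c(tiers, rep(k, sum(sel)))
        cur <- cur[!sel]
        if (length(cur) > 0L)
            cur <- cur / sum(cur)
    }
    out <- data.frame(gene = genes, score = unname(v[genes]), tier = tiers,
                      stringsAsFactors = FALSE)
    out <- out[order(out$tier, -out$score, out$gene), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "thresholds") <- thresholds
    attr(out, "remainder") <- remainder
    out
}

#' Check the Markov mass bound behind the tier threshold
#'
#' For any distribution \eqn{P} and \eqn{\varepsilon > 0}, Markov's
#' inequality gives
#' \eqn{\sum_{P(g) \le 2^{-(1+\varepsilon) H(P)}} P(g) \le 1/(1+\varepsilon)},
#' i.e. the genes above the relaxed entropy threshold carry at least
#' \eqn{1 - 1/(1+\varepsilon)} of the mass.  This justifies reading a tier
#' as "the few genes the distribution is effectively concentrated on".
#' Exposed as a checkable property, not a pipeline stage.
#'
#' @param p A normalized \linkS4class{ScoreVector} or named numeric
#'   distribution.
#' @param epsilon Positive relaxation parameter.
#' @return \code{TRUE} if the bound holds (it must, up to floating-point
#'   slack).
#' @export
markovMassBound <- function(p, epsilon) {
    stopifnot(epsilon > 0)
    v <- if (is(p, "ScoreVector")) scoreValues(p) else p
    v <- v[v > 0]
    h <- -sum(v * log2(v))
    ## Markov's inequality needs a positive threshold exponent; a point
    ## mass (H = 0) is already focused, so the bound is vacuously true
    if (h == 0)
        return(TRUE)
    thr <- 2^(-(1 + epsilon) * h)
    sum(v[v <= thr]) <= 1 / (1 + epsilon) + 1e-12
}
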