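## Shared fixtures and independent oracles for the test suite.

## Build a GeneModel by writing a temporary BED and reading it back,
## so fixtures go through the public reader.
makeModel <- function(symbols,
                      chrom = rep("chr1", length(symbols)),
                      start = (seq_along(symbols) - 1L) * 1000L,
                      end = start + 500L) {
    bed <- tempfile(fileext = ".bed")
    writeLines(paste(chrom, start, end, symbols, sep = "\t"), bed)
    readGeneModel(bed, format = "bed")
}

## uniform ScoreVector over a symbol set
unifOver <- function(symbols) {
    ScoreVector(setNames(rep(1 / length(symbols), length(symbols)),
                         symbols), role = "prior")
}

makeLesions <- function(...) {
    args <- list(...)
    lapply(args, function(a) list(amplitude = a$amplitude, genes = a$genes))
}

## --- independent brute-force oracles -------------------------------------
## Term-by-term evaluation of the posterior definitions, written against
## the formulas directly (explicit double loops, no shared code with the
## implementation).  `prior` is a named numeric distribution.

oracleRecurrence <- function(lesions, prior) {
    genes <- names(prior)
    num <- setNames(numeric(length(genes)), genes)
    denom <- 0
    for (les in lesions) {
        C <- les$amplitude
        for (G in les$genes)
            denom <- denom + C * prior[[G]]
        for (g in genes)
            if (g %in% les$genes)
                num[[g]] <- num[[g]] + C * prior[[g]]
    }
    if (denom == 0) return(num)
    v <- num / denom
    v / sum(v)
}

oracleFocality <- function(lesions, prior) {
    genes <- names(prior)
    val <- setNames(numeric(length(genes)), genes)
    ampTotal <- 0
    for (les in lesions) {
        mass <- 0
        for (G in les$genes) mass <- mass + prior[[G]]
        if (mass > 0) ampTotal <- ampTotal + les$amplitude
    }
    if (ampTotal == 0) return(val)
    for (les in lesions) {
        mass <- 0
        for (G in les$genes) mass <- mass + prior[[G]]
        if (mass == 0) next
        for (g in genes)
            if (g %in% les$genes)
                val[[g]] <- val[[g]] +
                    (les$amplitude / ampTotal) * prior[[g]] / mass
    }
    val / sum(val)
}

## Random disjoint-lesion instance over at most `maxGenes` genes.
randomInstance <- function(maxGenes = 20, maxLesions = 6, amps = 1:3,
                           uniformPriorOnly = FALSE) {
    nG <- sample(2:maxGenes, 1)
    symbols <- sprintf("g%02d", seq_len(nG))
    nL <- sample(seq_len(min(maxLesions, nG)), 1)
    pool <- sample(symbols)
    sizes <- diff(sort(c(0, sample(seq_len(nG - 1), nL - 1), nG)))
    at <- cumsum(c(1, sizes[-nL]))
    lesions <- lapply(seq_len(nL), function(i) {
        list(amplitude = sample(amps, 1),
             genes = pool[at[i]:(at[i] + sizes[i] - 1)])
    })
    prior <- if (uniformPriorOnly) rep(1, nG) else runif(nG, 0.1, 1)
    prior <- setNames(prior / sum(prior), symbols)
    list(symbols = symbols, lesions = lesions, prior = prior)
}

## fixture paths shipped with the package
fixturePath <- function(file) {
    system.file("extdata", file, package = "focalDrivers", mustWork = TRUE)
}
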