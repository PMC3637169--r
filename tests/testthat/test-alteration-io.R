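segFile <- function(rows) {
    path <- tempfile(fileext = ".seg")
    writeLines(c("sample\tchromosome\tstart\tend\tvalue", rows), path)
    path
}

test_that("readSeg parses, converts coordinates and handles modes", {
    ## empty file with header
    expect_equal(nrow(readSeg(segFile(character()))), 0)
    ## 1-based inclusive -> 0-based half-open
    df <- readSeg(segFile("s1\tchr1\t101\t200\t3"))
    expect_equal(df$start, 100)
    expect_equal(df$end, 200)
    expect_equal(df$cn, 3)
    ## log2 ratio -1 at ploidy 2 is one absolute copy
    df <- readSeg(segFile("s1\tchr1\t1\t100\t-1"), mode = "log2ratio",
                  ploidy = 2)
    expect_equal(df$cn, 1)
    ## row errors are line-numbered; missing columns are named
    expect_error(readSeg(segFile("s1\tchr1\t200\t100\t3")), "line 2")
    expect_error(readSeg(segFile("s1\tchr1\t1\t100\tabc")), "line 2")
    bad <- tempfile()
    writeLines(c("sample\tchromosome\tstart\tend", "s1\tchr1\t1\t2"), bad)
    expect_error(readSeg(bad), "value")
})

test_that("discretizeAmplitude follows the copy-deviation rule", {
    d <- discretizeAmplitude(c(0, 1, 3, 2.2, 2, 6), ploidy = 2)
    expect_identical(d$type,
                     c("deletion", "deletion", "gain", "none", "none", "gain"))
    expect_identical(d$amplitude, c(2L, 1L, 1L, 0L, 0L, 4L))
    ## half-up rounding, not banker's
    expect_identical(discretizeAmplitude(2.5)$amplitude, 1L)
    expect_identical(discretizeAmplitude(3.5)$amplitude, 2L)
    ## deletions capped at ploidy even for impossible inputs
    expect_identical(discretizeAmplitude(0, ploidy = 4)$amplitude, 4L)
})

test_that("discretization is exact on integer copy numbers", {
    for (cn in 0:6) {
        d <- discretizeAmplitude(cn, ploidy = 2)
        back <- switch(d$type,
                       none = 2, gain = 2 + d$amplitude,
                       deletion = 2 - d$amplitude)
        expect_equal(back, cn)
    }
})

test_that("buildLesionSets maps segments to disjoint gene lesions", {
    gm <- makeModel(paste0("g", 1:6))  # g_i spans [(i-1)*1000, (i-1)*1000+500)
    segs <- data.frame(
        sample = "s1",
        chromosome = "chr1",
        start = c(0, 4000),
        end = c(500, 5500),
        cn = c(0, 3), stringsAsFactors = FALSE)
    sets <- buildLesionSets(segs, gm)
    del <- lesionList(sets$s1$deletion)
    gain <- lesionList(sets$s1$gain)
    expect_length(del, 1)
    expect_identical(del[[1]]$genes, "g1")
    expect_equal(del[[1]]$amplitude, 2)
    expect_length(gain, 1)
    expect_identical(gain[[1]]$genes, c("g5", "g6"))
    expect_equal(gain[[1]]$amplitude, 1)
})

test_that("overlapping same-type segments merge with max amplitude", {
    gm <- makeModel(paste0("g", 1:4))
    segs <- data.frame(
        sample = "s1", chromosome = "chr1",
        start = c(0, 1000), end = c(1500, 2500),
        cn = c(3, 4), stringsAsFactors = FALSE)  # {g1,g2} D1, {g2,g3} D2
    sets <- buildLesionSets(segs, gm)
    gain <- lesionList(sets$s1$gain)
    expect_length(gain, 1)
    expect_setequal(gain[[1]]$genes, c("g1", "g2", "g3"))
    expect_equal(gain[[1]]$amplitude, 2)
})

test_that("segments in gene deserts or at baseline contribute nothing", {
    gm <- makeModel(paste0("g", 1:4))
    segs <- data.frame(sample = "s1", chromosome = "chr1",
                       start = c(600, 0), end = c(900, 500),
                       cn = c(5, 2), stringsAsFactors = FALSE)
    sets <- buildLesionSets(segs, gm)
    expect_length(lesionList(sets$s1$gain), 0)
    expect_length(lesionList(sets$s1$deletion), 0)
})

test_that("lesion gene sets are pairwise disjoint on random segment soups", {
    set.seed(21)
    gm <- makeModel(sprintf("g%03d", 1:100))
    for (rep in 1:10) {
        n <- 30
        start <- sample(0:95000, n, replace = TRUE)
        segs <- data.frame(
            sample = sample(c("a", "b"), n, replace = TRUE),
            chromosome = "chr1",
            start = start, end = start + sample(500:20000, n, replace = TRUE),
            cn = sample(c(0, 1, 3, 4), n, replace = TRUE),
            stringsAsFactors = FALSE)
        sets <- buildLesionSets(segs, gm)
        for (s in names(sets)) {
            for (type in c("gain", "deletion")) {
                genes <- unlist(lapply(lesionList(sets[[s]][[type]]),
                                       `[[`, "genes"))
                expect_false(anyDuplicated(genes) > 0)
            }
        }
    }
})

mafFile <- function(rows) {
    path <- tempfile(fileext = ".maf")
    writeLines(c("Hugo_Symbol\tTumor_Sample_Barcode\tVariant_Classification",
                 rows), path)
    path
}

test_that("readMutations filters classes and harmonizes symbols", {
    maf <- mafFile(c("TP53\ts1\tSilent", "MYC\ts1\tMissense_Mutation"))
    rec <- readMutations(maf, format = "maf")
    expect_equal(nrow(rec), 1)
    expect_identical(rec$gene, "MYC")
    ## TSV without a classification column keeps everything
    tsv <- tempfile(fileext = ".tsv")
    writeLines(c("sample\tgene", "s1\tg1", "s2\tg2"), tsv)
    expect_equal(nrow(readMutations(tsv, format = "tsv")), 2)
    ## symbols absent from the model are dropped with a message
    gm <- makeModel(c("g1", "g2"))
    writeLines(c("sample\tgene", "s1\tg1", "s1\tnovel"), tsv)
    expect_message(rec <- readMutations(tsv, format = "tsv", model = gm),
                   "1 mutation record")
    expect_identical(rec$gene, "g1")
    ## missing required columns are named
    bad <- tempfile()
    writeLines(c("sample\tsymbol", "s1\tg1"), bad)
    expect_error(readMutations(bad, format = "tsv"), "gene")
})

test_that("filterRecurrent counts distinct samples, not mutations", {
    rec <- data.frame(
        sample = c("s1", "s2", "s1", "s1", "s1", "s1"),
        gene = c("geneA", "geneA", "geneB", "geneC", "geneC", "geneC"),
        classification = NA_character_, stringsAsFactors = FALSE)
    out <- filterRecurrent(rec, minSamples = 2)
    expect_setequal(out$gene, "geneA")   # geneC: 3 hits but 1 sample
    expect_equal(nrow(out), 2)
    ## minSamples = 1 is the per-sample de-duplicated identity
    out1 <- filterRecurrent(rec, minSamples = 1)
    expect_equal(nrow(out1), 4)
})

test_that("mutationLesionSets builds singleton lesions with amplitude modes", {
    rec <- data.frame(sample = c("s1", "s1", "s2", "s2", "s2"),
                      gene = c("g1", "g2", "g1", "g1", "g1"),
                      stringsAsFactors = FALSE)
    sets <- mutationLesionSets(rec)
    expect_length(lesionList(sets$s1), 2)
    amps <- vapply(lesionList(sets$s1), `[[`, numeric(1), "amplitude")
    expect_equal(amps, c(1, 1))
    expect_equal(lesionList(sets$s2)[[1]]$amplitude, 1)
    ## count mode keeps multiplicity
    setsC <- mutationLesionSets(rec, mode = "count")
    expect_equal(lesionList(setsC$s2)[[1]]$amplitude, 3)
    ## empty input -> empty mapping
    expect_length(mutationLesionSets(rec[0, ]), 0)
})
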