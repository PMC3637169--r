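test_that("recurrence posterior matches hand-evaluated weighted formula", {
    u <- unifOver(paste0("g", 1:4))
    ls <- LesionSet("s1", "gain", makeLesions(
        list(amplitude = 2, genes = "g1"),
        list(amplitude = 1, genes = c("g2", "g3"))))
    v <- scoreValues(recurrencePosterior(ls, u))
    ## T = 2*1 + 1*2 = 4
    expect_equal(unname(v), c(2/4, 1/4, 1/4, 0), tolerance = 1e-12)
})

test_that("unit-amplitude uniform-prior scores equal 1/K and 1/(t*L)", {
    ## three lesions of one, two and one genes
    u <- unifOver(paste0("g", 1:4))
    ls <- LesionSet("s1", "gain", makeLesions(
        list(amplitude = 1, genes = "g1"),
        list(amplitude = 1, genes = c("g2", "g3")),
        list(amplitude = 1, genes = "g4")))
    r <- scoreValues(recurrencePosterior(ls, u))
    f <- scoreValues(focalityPosterior(ls, u))
    expect_equal(unname(r), rep(1/4, 4), tolerance = 1e-12)
    expect_equal(unname(f), c(1/3, 1/6, 1/6, 1/3), tolerance = 1e-12)
})

test_that("focality posterior matches hand-evaluated weighted formula", {
    u <- unifOver(paste0("g", 1:4))
    ls <- LesionSet("s1", "gain", makeLesions(
        list(amplitude = 2, genes = "g1"),
        list(amplitude = 1, genes = c("g2", "g3"))))
    v <- scoreValues(focalityPosterior(ls, u))
    expect_equal(unname(v), c(2/3, 1/6, 1/6, 0), tolerance = 1e-12)
    ## single whole-mass lesion
    one <- LesionSet("s1", "gain", makeLesions(
        list(amplitude = 1, genes = "g2")))
    expect_equal(unname(scoreValues(focalityPosterior(one, u))),
                 c(0, 1, 0, 0))
})

test_that("zero-prior genes get zero posterior; all-zero lesions give the empty vector", {
    prior <- ScoreVector(c(g1 = 1, g2 = 0), role = "prior")
    ls <- LesionSet("s1", "gain", makeLesions(
        list(amplitude = 1, genes = "g1"),
        list(amplitude = 1, genes = "g2")))
    expect_equal(scoreValues(recurrencePosterior(ls, prior)),
                 c(g1 = 1, g2 = 0))
    expect_equal(scoreValues(focalityPosterior(ls, prior)),
                 c(g1 = 1, g2 = 0))
    only2 <- LesionSet("s1", "gain", makeLesions(
        list(amplitude = 1, genes = "g2")))
    expect_true(isEmptyScore(recurrencePosterior(only2, prior)))
    expect_true(isEmptyScore(focalityPosterior(only2, prior)))
})

test_that("non-disjoint lesion sets are rejected", {
    expect_error(LesionSet("s1", "gain", makeLesions(
        list(amplitude = 1, genes = c("g1", "g2")),
        list(amplitude = 1, genes = "g2"))), "disjoint")
})

test_that("posteriors match the brute-force oracle on random instances", {
    set.seed(31)
    for (rep in 1:200) {
        inst <- randomInstance()
        ls <- LesionSet("s", "gain", inst$lesions)
        prior <- ScoreVector(inst$prior, role = "prior")
        expect_equal(scoreValues(recurrencePosterior(ls, prior)),
                     oracleRecurrence(inst$lesions, inst$prior),
                     tolerance = 1e-12)
        expect_equal(scoreValues(focalityPosterior(ls, prior)),
                     oracleFocality(inst$lesions, inst$prior),
                     tolerance = 1e-12)
    }
})

test_that("recurrence is partition-invariant; focality favors small lesions", {
    u <- unifOver(paste0("g", 1:6))
    split3 <- LesionSet("s", "gain", makeLesions(
        list(amplitude = 1, genes = "g1"),
        list(amplitude = 1, genes = c("g2", "g3")),
        list(amplitude = 1, genes = c("g4", "g5", "g6"))))
    lumped <- LesionSet("s", "gain", makeLesions(
        list(amplitude = 1, genes = paste0("g", 1:6))))
    expect_equal(scoreValues(recurrencePosterior(split3, u)),
                 scoreValues(recurrencePosterior(lumped, u)))
    f <- scoreValues(focalityPosterior(split3, u))
    expect_gt(f[["g1"]], f[["g2"]])
    expect_gt(f[["g2"]], f[["g4"]])
})

test_that("posteriors are invariant to a common amplitude rescaling", {
    set.seed(32)
    for (rep in 1:20) {
        inst <- randomInstance()
        prior <- ScoreVector(inst$prior, role = "prior")
        scaled <- lapply(inst$lesions, function(l) {
            l$amplitude <- l$amplitude * 7.5
            l
        })
        expect_equal(
            scoreValues(recurrencePosterior(
                LesionSet("s", "gain", inst$lesions), prior)),
            scoreValues(recurrencePosterior(
                LesionSet("s", "gain", scaled), prior)),
            tolerance = 1e-12)
        expect_equal(
            scoreValues(focalityPosterior(
                LesionSet("s", "gain", inst$lesions), prior)),
            scoreValues(focalityPosterior(
                LesionSet("s", "gain", scaled), prior)),
            tolerance = 1e-12)
    }
})

test_that("aggregation is the mean of per-sample distributions", {
    a <- ScoreVector(c(g1 = 1, g2 = 0))
    b <- ScoreVector(c(g1 = 0.5, g2 = 0.5))
    agg <- aggregatePosteriors(list(a, b))
    expect_equal(scoreValues(agg), c(g1 = 3/4, g2 = 1/4))
    ## idempotent on identical inputs, order-invariant
    expect_equal(scoreValues(aggregatePosteriors(list(b, b, b))),
                 scoreValues(b))
    expect_equal(scoreValues(aggregatePosteriors(list(b, a))),
                 scoreValues(agg))
    ## empty vectors are excluded; nothing usable is an error
    z <- ScoreVector(c(g1 = 0, g2 = 0))
    expect_equal(scoreValues(aggregatePosteriors(list(a, z))),
                 scoreValues(a))
    expect_error(aggregatePosteriors(list(z)), "no scorable samples")
})

test_that("combineScores multiplies and renormalizes", {
    a <- ScoreVector(c(g1 = 3/4, g2 = 1/4))
    expect_equal(scoreValues(combineScores(a, a)),
                 c(g1 = 9/10, g2 = 1/10), tolerance = 1e-12)
    ## uniform is the multiplicative identity
    u <- ScoreVector(c(g1 = 1/2, g2 = 1/2))
    expect_equal(scoreValues(combineScores(a, u)), scoreValues(a),
                 tolerance = 1e-12)
    expect_error(combineScores(ScoreVector(c(g1 = 1, g2 = 0)),
                               ScoreVector(c(g1 = 0, g2 = 1))),
                 "disjoint supports")
})

test_that("mutation scores give 1/N per sample and coincide across posteriors", {
    u <- unifOver(c("g1", "g2"))
    sets <- mutationLesionSets(data.frame(
        sample = c("s1", "s1", "s2"), gene = c("g1", "g2", "g1"),
        stringsAsFactors = FALSE))
    ms <- mutationScores(sets, u)
    expect_equal(scoreValues(ms), c(g1 = 3/4, g2 = 1/4))
    ## single-gene lesions: recurrence == focality for every sample
    for (s in sets)
        expect_equal(scoreValues(recurrencePosterior(s, u)),
                     scoreValues(focalityPosterior(s, u)))
})

test_that("integration multiplies mutation by the R+F sum", {
    m <- ScoreVector(c(g1 = 3/4, g2 = 1/4))
    flat <- ScoreVector(c(g1 = 1/2, g2 = 1/2))
    ## uniform R+F preserves the mutation vector
    expect_equal(scoreValues(integrateMutCn(m, flat, flat)),
                 scoreValues(m), tolerance = 1e-12)
    ## hand-computed: (1/2,1/2) x (R+F = 3/2,1/2) -> (3/4, 1/4)
    r <- ScoreVector(c(g1 = 3/4, g2 = 1/4))
    f <- ScoreVector(c(g1 = 3/4, g2 = 1/4))
    out <- integrateMutCn(ScoreVector(c(g1 = 1/2, g2 = 1/2)), r, f)
    expect_equal(scoreValues(out), c(g1 = 3/4, g2 = 1/4),
                 tolerance = 1e-12)
    ## genes without mutation support get zero
    m0 <- ScoreVector(c(g1 = 1, g2 = 0))
    expect_equal(scoreValues(integrateMutCn(m0, r, f)), c(g1 = 1, g2 = 0))
})

test_that("every produced ScoreVector is normalized within 1e-9", {
    set.seed(33)
    for (rep in 1:50) {
        inst <- randomInstance()
        prior <- ScoreVector(inst$prior, role = "prior")
        ls <- LesionSet("s", "gain", inst$lesions)
        for (v in list(recurrencePosterior(ls, prior),
                       focalityPosterior(ls, prior)))
            expect_lt(abs(sum(scoreValues(v)) - 1), 1e-9)
    }
})

test_that("heuristic mode reproduces hand-computed D/L and D/T sums", {
    gm <- makeModel(paste0("g", 1:4))
    s1 <- LesionSet("s1", "gain", makeLesions(
        list(amplitude = 2, genes = "g1"),
        list(amplitude = 1, genes = c("g2", "g3"))))
    s2 <- LesionSet("s2", "gain", makeLesions(
        list(amplitude = 1, genes = "g1")))
    ## focality D/L: s1 gives g1 2, g2 g3 1/2 each; s2 gives g1 1
    f <- scoreValues(heuristicScores(list(s1, s2), gm, "focality"))
    expect_equal(unname(f), c(3, 0.5, 0.5, 0) / 4, tolerance = 1e-12)
    ## recurrence D/T: s1 T = 4 -> g1 1/2, g2 g3 1/4; s2 -> g1 1
    r <- scoreValues(heuristicScores(list(s1, s2), gm, "recurrence"))
    expect_equal(unname(r), c(1.5, 0.25, 0.25, 0) / 2, tolerance = 1e-12)
})
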