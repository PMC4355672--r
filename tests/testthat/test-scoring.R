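test_that("group summaries give arithmetic means and n-1 SDs", {
    x <- TimeCourseExperiment(
        matrix(c(2, 4, 5, 5, 5, 7, 1, 3, 2, 2, 8, 9), 6, 2,
               dimnames = list(NULL, c("F1", "F2"))),
        group = c("C", "C", "M", "M", "M", "M"),
        timePoint = c(0, 0, 0, 0, 1, 1))
    gs <- suppressMessages(groupSummary(x))
    expect_equal(unname(gs@muC[, 1]), c(3, 2))
    expect_true(all(is.na(gs@muC[, 2])))    # no C samples at time point 1
    expect_equal(unname(gs@sdC["F1", 1]), sqrt(2))
    expect_equal(unname(gs@muM["F1", 1]), 5)
    expect_equal(unname(gs@sdM["F1", 1]), 0)
    expect_message(groupSummary(x[, timePoint(x) == 0 |
                                    seq_len(ncol(x)) == 5]),
                   "singleton")
})

test_that("worked scoring examples reproduce", {
    # D = 1, S = 0, epsilon = 0.005 -> 200
    gs <- GroupSummary(muC = rbind(c(0, 0)), muM = rbind(c(1, 1)))
    expect_equal(wrdaScore(gs, explicitWeights(c(0.5, 0.5)))$score, 200)
    # identical groups -> 0
    gs <- GroupSummary(muC = rbind(c(3, 4)), muM = rbind(c(3, 4)),
                       sdC = rbind(c(1, 1)), sdM = rbind(c(1, 1)))
    expect_identical(wrdaScore(gs, explicitWeights(c(0.5, 0.5)))$score, 0)
    # D = 1.25, S = 2, eps = 0 -> 0.625
    gs <- GroupSummary(muC = rbind(c(1, 2)), muM = rbind(c(3, 1)),
                       sdC = rbind(c(1, 1)), sdM = rbind(c(1, 1)))
    expect_equal(wrdaScore(gs, explicitWeights(c(0.25, 0.75)),
                           epsilon = 0)$score, 0.625)
    # sampling-time layer: D = 3, S = 2, eps = 0 -> 1.5
    gs <- GroupSummary(muC = rbind(c(0, 0)), muM = rbind(c(2, 4)),
                       sdC = rbind(c(1, 1)), sdM = rbind(c(1, 1)),
                       timePoint = c(0L, 0L), samplingTime = c(0L, 1L))
    expect_equal(w2rdaScore(gs, explicitWeights(1),
                            k = explicitWeights(c(0.5, 0.5)),
                            epsilon = 0)$score, 1.5)
})

test_that("scores match the naively-looped reference on random data", {
    for (s in 1:30) {
        x <- randomTimeCourse(seed = 400 + s)
        N <- nTimePoints(x)
        omega <- randomScheme(N)
        kTemplate <- randomScheme(2)
        p <- vapply(sort(unique(timePoint(x))), function(i)
            length(unique(samplingTime(x)[timePoint(x) == i])), integer(1))
        kPer <- lapply(p, function(pi)
            weightValues(if (weightFamily(kTemplate) == "equal")
                makeWeights("equal", n = pi)
                else makeWeights(weightFamily(kTemplate),
                                 q = changingFactor(kTemplate), n = pi)))
        got <- w2rdaScore(x, omega, k = kTemplate)$score
        want <- naiveScores(x, weightValues(omega), kPer)
        expect_equal(got, want, tolerance = 1e-12)
    }
})

test_that("w2RDA reduces bit-identically to wRDA when p = 1", {
    for (s in 1:20) {
        x <- randomTimeCourse(seed = 700 + s, pMax = 1)
        omega <- randomScheme(nTimePoints(x))
        a <- wrdaScore(x, omega)
        b <- w2rdaScore(x, omega, k = explicitWeights(1))
        expect_identical(a$score, b$score)
        expect_identical(a$D, b$D)
        expect_identical(a$rank, b$rank)
    }
})

test_that("scores are scale-covariant in the weights", {
    x <- randomTimeCourse(seed = 31, pMax = 1)
    N <- nTimePoints(x)
    w0 <- makeWeights("linear", q = 0.4, n = N, normalize = FALSE)
    sc0 <- wrdaScore(x, w0, epsilon = 0)$score
    w1 <- explicitWeights(weightValues(w0) * 3.7)
    expect_equal(wrdaScore(x, w1, epsilon = 0)$score, sc0,
                 tolerance = 1e-12)
})

test_that("increasing a weighted mean gap never decreases the score", {
    gs <- GroupSummary(muC = rbind(c(1, 1, 1)), muM = rbind(c(2, 3, 1)),
                       sdC = rbind(c(1, 1, 1)), sdM = rbind(c(1, 1, 1)))
    omega <- explicitWeights(c(0.2, 0.5, 0.3))
    base <- wrdaScore(gs, omega)$score
    gs2 <- GroupSummary(muC = rbind(c(1, 1, 1)), muM = rbind(c(2, 5, 1)),
                        sdC = rbind(c(1, 1, 1)), sdM = rbind(c(1, 1, 1)))
    expect_gt(wrdaScore(gs2, omega)$score, base)
})

test_that("zero-weight time points are inert", {
    x <- randomTimeCourse(seed = 55, N = 5, pMax = 1)
    N <- nTimePoints(x)
    w <- c(0.5, 0.5, rep(0, N - 2))
    sc <- wrdaScore(x, explicitWeights(w))$score
    # perturb all data at a zero-weight time point
    mat <- assay(x)
    mat[, timePoint(x) == N - 1] <- mat[, timePoint(x) == N - 1] * 100 + 7
    y <- TimeCourseExperiment(t(mat), sampleGroup(x), timePoint(x),
                              samplingTime(x), featureIds = rownames(x))
    expect_identical(wrdaScore(y, explicitWeights(w))$score, sc)
})

test_that("ranking is a stable permutation with input-order tie-break", {
    gs <- GroupSummary(muC = matrix(0, 3, 2),
                       muM = matrix(c(3, 1, 3, 3, 1, 3), 3, 2))
    sc <- wrdaScore(gs, explicitWeights(c(0.5, 0.5)))
    expect_identical(sort(sc$rank), 1:3)
    expect_identical(sc$rank, c(1L, 3L, 2L))  # F1/F3 tie -> F1 first
    rownames(sc) <- paste0("F", 1:3)
    expect_identical(topFeatures(sc, 2), c("F1", "F3"))
    expect_error(topFeatures(sc, 4), "n must lie")
})

test_that("missing strata error only when they carry positive weight", {
    x <- randomTimeCourse(seed = 77, pMax = 1)
    N <- nTimePoints(x)
    y <- x[, !(sampleGroup(x) == "M" & timePoint(x) == N - 1)]
    wZero <- explicitWeights(c(rep(1, N - 1), 0) / (N - 1))
    expect_silent(sc <- wrdaScore(y, wZero))
    expect_error(wrdaScore(y, makeWeights("equal", n = N)),
                 sprintf("time point %d", N - 1))
})

test_that("epsilon must not be negative", {
    gs <- GroupSummary(muC = rbind(0), muM = rbind(1),
                       timePoint = 0L)
    expect_error(wrdaScore(gs, explicitWeights(1), epsilon = -1),
                 "epsilon")
})
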