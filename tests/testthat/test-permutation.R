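test_that("permutation nulls are seed-reproducible and non-negative", {
    x <- randomTimeCourse(seed = 12, pMax = 1)
    omega <- makeWeights("equal", n = nTimePoints(x))
    n1 <- permuteScores(x, omega, B = 25, seed = 5)
    n2 <- permuteScores(x, omega, B = 25, seed = 5)
    expect_identical(nullScores(n1), nullScores(n2))
    expect_true(all(nullScores(n1) >= 0))
    n3 <- permuteScores(x, omega, B = 25, seed = 6)
    expect_false(identical(nullScores(n1), nullScores(n3)))
})

test_that("constant data yield an all-zero null", {
    x <- TimeCourseExperiment(matrix(3, 8, 1, dimnames = list(NULL, "F1")),
                              group = rep(c("C", "M"), 4),
                              timePoint = rep(0:1, each = 4))
    null <- permuteScores(x, makeWeights("equal", n = 2), B = 10, seed = 1)
    expect_identical(unname(nullScores(null)), matrix(0, 10, 1))
})

test_that("null scores match the observed distribution under exchangeability", {
    # C and M drawn from the same distribution: permuting labels changes
    # nothing statistically
    sim <- simulateTimeCourse(ratDefaultSpec(nFeatures = 50, nSignal = 0,
                                             nTimePoints = 4,
                                             samplesC = 5, samplesM = 5),
                              seed = 42)
    omega <- makeWeights("equal", n = 4)
    obs <- wrdaScore(sim$dataset, omega)
    null <- permuteScores(sim$dataset, omega, B = 200, seed = 7)
    ks <- suppressWarnings(
        stats::ks.test(obs$score, as.vector(nullScores(null))))
    expect_gt(ks$p.value, 0.01)
})

test_that("FDR estimate reproduces the hand-counted example", {
    obs <- S4Vectors::DataFrame(score = c(10, 8, 2), rank = 1:3,
                                row.names = paste0("F", 1:3))
    null <- new("PermutationNull",
                nullScores = rbind(c(1, 9, 0), c(0, 0, 0)),
                B = 2L, seed = 1L, exhaustive = FALSE)
    # s_(2) = 8; exceedances 1 and 0; E[V] = 0.5; FDR = 0.25
    expect_equal(fdrAtN(obs, null, 2), 0.25)
    expect_identical(fdrAtN(obs, null, 1), 0)   # nothing reaches s_(1) = 10
    expect_error(fdrAtN(obs, null, 4), "n must lie")
})

test_that("FDR is zero when the null never reaches the threshold", {
    obs <- S4Vectors::DataFrame(score = c(5, 4, 3, 2, 1), rank = 1:5)
    null <- new("PermutationNull",
                nullScores = matrix(runif(25, 0, 0.9), 5), B = 5L,
                seed = 1L, exhaustive = FALSE)
    for (n in 1:5) expect_identical(fdrAtN(obs, null, n), 0)
})

test_that("sampled FDR agrees with exhaustive enumeration on tiny data", {
    # 8 samples, 2 time points: C(4,2)^2 = 36 distinct assignments
    x <- randomTimeCourse(seed = 91, F = 6, N = 2, pMax = 1, nPerGroup = 2)
    omega <- makeWeights("equal", n = 2)
    obs <- wrdaScore(x, omega)
    null <- permuteScores(x, omega, exhaustive = TRUE)
    expect_identical(null@B, 36L)

    # independent oracle: enumerate assignments by hand, score naively,
    # count exceedances
    grp <- sampleGroup(x); tp <- timePoint(x)
    idx0 <- which(tp == 0); idx1 <- which(tp == 1)
    naiveNull <- NULL
    for (a in combn(4, 2, simplify = FALSE))
        for (b in combn(4, 2, simplify = FALSE)) {
            g <- grp
            g[idx0] <- "M"; g[idx0[a]] <- "C"
            g[idx1] <- "M"; g[idx1[b]] <- "C"
            y <- TimeCourseExperiment(t(assay(x)), g, tp,
                                      featureIds = rownames(x))
            naiveNull <- rbind(naiveNull, naiveScores(y, c(0.5, 0.5)))
        }
    naiveObs <- naiveScores(x, c(0.5, 0.5))
    for (n in c(1, 3, 6)) {
        sn <- sort(naiveObs, decreasing = TRUE)[n]
        want <- min(1, mean(rowSums(naiveNull >= sn)) / n)
        expect_equal(fdrAtN(obs, null, n), want, tolerance = 1e-12)
    }
})

test_that("lowest FDR picks the minimum with largest-n ties", {
    obs <- S4Vectors::DataFrame(score = seq(100, 1, length.out = 100),
                                rank = 1:100)
    null <- new("PermutationNull", nullScores = matrix(0, 3, 100), B = 3L,
                seed = 1L, exhaustive = FALSE)
    out <- lowestFdr(obs, null, nGrid = c(50, 45, 40))
    expect_identical(out$fdr, 0)
    expect_identical(out$n, 50L)    # all tie at 0 -> largest n
    out <- lowestFdr(obs, null, nGrid = 30)
    expect_identical(out$n, 30L)
    expect_error(fdrCurve(obs, null, nGrid = integer(0)), "nonempty")
})

test_that("noise filter keeps planted signal and drops pure noise", {
    sim <- simulateTimeCourse(ratDefaultSpec(nFeatures = 1000, nSignal = 30,
                                             onset = 0), seed = 13)
    omega <- makeWeights("equal", n = 8)
    obs <- wrdaScore(sim$dataset, omega)
    null <- permuteScores(sim$dataset, omega, B = 100, seed = 14)
    kept <- noiseFilter(obs, null, quantile = 0.95)
    # planted features survive the filter...
    expect_gte(mean(sim$truth$signalFeatures %in% kept), 0.9)
    # ...and noise is retained at roughly the nominal 5% rate
    noiseKept <- sum(!kept %in% sim$truth$signalFeatures)
    expect_lt(noiseKept, 0.15 * (1000 - 30))
    # rank-ordered output
    expect_identical(kept, topFeatures(obs, nrow(obs))[
        topFeatures(obs, nrow(obs)) %in% kept])
    expect_error(noiseFilter(obs, null, quantile = 1.2), "quantile")
})
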