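test_that("two-level analysis promotes stage-specific features at level 2", {
    # planted features diverge ONLY at the three level-2-weighted points
    spec <- ratDefaultSpec(nFeatures = 150, nSignal = 15, delta = 0)
    sim <- simulateTimeCourse(spec, seed = 61)
    x <- sim$dataset
    mat <- assay(x)
    ids <- sim$truth$signalFeatures
    sdF <- apply(mat, 1, sd)
    hit <- sampleGroup(x) == "M" & timePoint(x) %in% c(2, 5, 7)
    mat[ids, hit] <- mat[ids, hit] + 1.2 * sdF[ids]
    x <- TimeCourseExperiment(t(mat), sampleGroup(x), timePoint(x),
                              samplingTime(x), featureIds = rownames(x))
    w2 <- c(0, 0, 0.3, 0, 0, 0.3, 0, 0.4)
    res <- runTwoLevel(x, level2Omega = w2, topN = 15, B = 60, seed = 62)
    l1 <- res$level1[ids, "rank"]
    l2rank <- res$level2[intersect(ids, rownames(res$level2)), "rank"]
    expect_lt(median(l2rank), median(l1))
    expect_gte(mean(ids %in% res$level2Top), 0.8)
    # level 2 operates within subset1's universe
    expect_true(all(rownames(res$level2) %in% res$subset1))
})

test_that("two consecutive two-level runs are identical", {
    sim <- simulateTimeCourse(ratDefaultSpec(nFeatures = 80, nSignal = 10),
                              seed = 63)
    w2 <- c(0, 0, 0.3, 0, 0, 0.3, 0, 0.4)
    r1 <- runTwoLevel(sim$dataset, w2, topN = 10, B = 40, seed = 64)
    r2 <- runTwoLevel(sim$dataset, w2, topN = 10, B = 40, seed = 64)
    expect_identical(r1$subset1, r2$subset1)
    expect_identical(r1$level2Top, r2$level2Top)
    expect_identical(nullScores(r1$null), nullScores(r2$null))
})

test_that("zero-weight time points do not affect level-2 ranks", {
    sim <- simulateTimeCourse(ratDefaultSpec(nFeatures = 60, nSignal = 8),
                              seed = 65)
    x <- sim$dataset
    w2 <- explicitWeights(c(0, 0, 0.3, 0, 0, 0.3, 0, 0.4))
    base <- w2rdaScore(x, w2)
    mat <- assay(x)
    off <- timePoint(x) %in% c(0, 1, 3, 4, 6)
    mat[, off] <- mat[, off] * 5 + 11
    y <- TimeCourseExperiment(t(mat), sampleGroup(x), timePoint(x),
                              samplingTime(x), featureIds = rownames(x))
    expect_identical(w2rdaScore(y, w2)$rank, base$rank)
    expect_identical(w2rdaScore(y, w2)$score, base$score)
})

test_that("SVM validation separates separable classes and is deterministic", {
    sim <- simulateTimeCourse(ratDefaultSpec(nFeatures = 40, nSignal = 20,
                                             nTimePoints = 2, samplesC = 20,
                                             samplesM = 20, delta = 2,
                                             onset = 0), seed = 66)
    panel <- sim$truth$signalFeatures
    v1 <- svmValidate(sim$dataset, panel, folds = 5, repeats = 10, seed = 67)
    expect_gt(v1$mean, 0.9)
    v2 <- svmValidate(sim$dataset, panel, folds = 5, repeats = 10, seed = 67)
    expect_identical(v1$accuracies, v2$accuracies)
    expect_length(v1$accuracies, 10L)
    expect_true(all(v1$accuracies >= 0 & v1$accuracies <= 1))
})

test_that("SVM accuracy collapses to chance under shuffled labels", {
    sim <- simulateTimeCourse(ratDefaultSpec(nFeatures = 30, nSignal = 15,
                                             nTimePoints = 2, samplesC = 20,
                                             samplesM = 20, delta = 2,
                                             onset = 0), seed = 68)
    x <- sim$dataset
    set.seed(69)
    y <- TimeCourseExperiment(t(assay(x)), sample(sampleGroup(x)),
                              timePoint(x), samplingTime(x),
                              featureIds = rownames(x))
    v <- svmValidate(y, sim$truth$signalFeatures, folds = 5, repeats = 10,
                     seed = 70)
    expect_lt(abs(v$mean - 0.5), 0.12)
})

test_that("ROC/AUC handles the canonical cases", {
    expect_identical(rocAuc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
    expect_identical(rocAuc(c(0, 1, 0, 1), rep(0.5, 4))$auc, 0.5)
    expect_equal(rocAuc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))$auc, 0.75)
    expect_error(rocAuc(c(1, 1), c(0.2, 0.3)), "both classes")
    pts <- rocAuc(c(0, 1, 1, 0), c(0.2, 0.9, 0.6, 0.4))$points
    expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
    expect_identical(c(pts$fpr[1], pts$tpr[1]), c(0, 0))
    expect_identical(c(pts$fpr[nrow(pts)], pts$tpr[nrow(pts)]), c(1, 1))
})

test_that("midrank AUC equals pROC on random vectors", {
    skip_if_not_installed("pROC")
    set.seed(71)
    for (r in 1:20) {
        lab <- c(rep(1, 6), rep(0, 7))
        sc <- round(rnorm(13), 1)       # forces ties
        got <- rocAuc(lab, sc)$auc
        want <- as.numeric(suppressMessages(
            pROC::auc(pROC::roc(lab, sc, levels = c(0, 1),
                                direction = "<"))))
        expect_equal(got, want, tolerance = 1e-12)
    }
})

test_that("report tables expose stage-specific vs pooled p-values", {
    sim <- simulateTimeCourse(ratDefaultSpec(nFeatures = 50, nSignal = 10,
                                             onset = 0, delta = 2),
                              seed = 72)
    sc <- wrdaScore(sim$dataset, makeWeights("equal", n = 8))
    rt <- reportTables(sim$dataset, sc, n = 10)
    expect_identical(nrow(rt), 10L)
    planted <- rownames(rt) %in% sim$truth$signalFeatures
    # divergence spans all points: pooling adds power
    expect_lt(median(rt$pPooled[planted]), median(rt$pT0[planted]))
    expect_warning(reportTables(sim$dataset, sc, n = 100), "clipped")
})
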