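#' Two-level noise-filter-then-reweight analysis
#'
#' Orchestrates the two-level ranking strategy for single-batch designs.
#' Level 1 scores every feature with equal time-point weights (1/N each),
#' builds a stratified permutation null, and drops features whose scores
#' are indistinguishable from label noise ([noiseFilter()]); the
#' survivors form feature subset 1. Level 2 rescores subset 1 with an
#' explicit weight vector that concentrates mass on the stages of
#' interest (e.g. 0.3/0.3/0.4 on three disease-defining time points and 0
#' elsewhere), so the final ranking targets features that discriminate at
#' exactly those stages.
#'
#' @inheritParams permuteScores
#' @param level2Omega numeric weight vector of length N (zeros allowed)
#'   or an explicit \linkS4class{WeightScheme} for the level-2 rescoring
#' @param topN how many top features to report from each level (clipped,
#'   with a warning, when fewer features are available)
#' @param noiseQuantile pooled-null quantile for the level-1 filter
#' @return a list with elements \code{subset1} (retained feature ids),
#'   \code{level1}, \code{level2} (score tables), \code{level1Top},
#'   \code{level2Top} (feature id vectors), \code{null}
#'   (the \linkS4class{PermutationNull}) and \code{fdrCurve}
#' @export
runTwoLevel <- function(x, level2Omega, topN = 20, B = 200,
                        noiseQuantile = 0.95, epsilon = 0.005, seed = 1) {
    stopifnot(is(x, "TimeCourseExperiment"))
    N <- nTimePoints(x)
    omega1 <- makeWeights("equal", n = N)
    omega2 <- if (is(level2Omega, "WeightScheme")) level2Omega
              else explicitWeights(level2Omega)
    if (length(weightValues(omega2)) != N)
        stop(sprintf("level-2 weights address %d time points but data have %d",
                     length(weightValues(omega2)), N))
    level1 <- w2rdaScore(x, omega1, epsilon = epsilon)
    null <- permuteScores(x, omega1, epsilon = epsilon, B = B, seed = seed)
    subset1 <- noiseFilter(level1, null, quantile = noiseQuantile)
    nMax <- min(length(subset1), nrow(level1))
    xs <- x[subset1, ]
    level2 <- w2rdaScore(xs, omega2, epsilon = epsilon)
    clip <- function(n, avail, what) {
        if (n > avail) {
            warning(sprintf("topN = %d clipped to %d available %s features",
                            n, avail, what))
            avail
        } else n
    }
    crv <- fdrCurve(level1, null,
                    nGrid = unique(pmin(c(50, 45, 40, 35, 30), nrow(level1))))
    list(subset1 = subset1,
         level1 = level1,
         level2 = level2,
         level1Top = topFeatures(level1, clip(topN, nrow(level1), "level-1")),
         level2Top = if (length(subset1))
             topFeatures(level2, clip(topN, nrow(level2), "level-2"))
             else character(0),
         null = null,
         fdrCurve = crv)
}

.stratifiedFolds <- function(labels, folds) {
    assign <- integer(length(labels))
    for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
    assign
}

#' Repeated cross-validated SVM assessment of a feature panel
#'
#' Measures how well the selected features separate the two groups:
#' stratified k-fold cross-validation of a support vector machine
#' (RBF kernel by default, features standardized on each training fold
#' only) repeated \code{repeats} times with freshly drawn folds, giving a
#' mean and SD of the per-repeat accuracies. Deterministic given
#' \code{seed}.
#'
#' @param x a \linkS4class{TimeCourseExperiment}
#' @param featureIds features forming the panel
#' @param folds number of CV folds (default 5)
#' @param repeats number of repetitions (default 50)
#' @param seed RNG seed for the fold draws
#' @param kernel SVM kernel, "radial" (default) or "linear"
#' @return a list with \code{accuracies} (per repeat), \code{mean},
#'   \code{sd}, \code{folds}, \code{repeats}
#' @export
svmValidate <- function(x, featureIds, folds = 5, repeats = 50, seed = 1,
                        kernel = c("radial", "linear")) {
    stopifnot(is(x, "TimeCourseExperiment"))
    kernel <- match.arg(kernel)
    missing <- setdiff(featureIds, rownames(x))
    if (length(missing))
        stop(sprintf("unknown feature id(s): %s",
                     paste(missing, collapse = ", ")))
    labels <- factor(sampleGroup(x), levels = c("C", "M"))
    if (any(table(labels) < 2L))
        stop("at least two samples per class are required")
    dat <- t(assay(x, "intensity")[featureIds, , drop = FALSE])
    set.seed(seed)
    accuracies <- vapply(seq_len(repeats), function(r) {
        fold <- .stratifiedFolds(labels, folds)
        correct <- 0L; total <- 0L
        for (f in seq_len(folds)) {
            test <- fold == f
            if (!any(test)) next
            fit <- e1071::svm(dat[!test, , drop = FALSE], labels[!test],
                              kernel = kernel, scale = TRUE)
            pred <- predict(fit, dat[test, , drop = FALSE])
            correct <- correct + sum(pred == labels[test])
            total <- total + sum(test)
        }
        correct / total
    }, numeric(1))
    list(accuracies = accuracies, mean = mean(accuracies),
         sd = stats::sd(accuracies), folds = folds, repeats = repeats)
}

#' ROC curve and AUC by midrank concordance
#'
#' The AUC is the probability that a randomly chosen positive sample
#' scores above a randomly chosen negative one, with ties counting 1/2 —
#' the Mann-Whitney statistic divided by n1*n0, computed via midranks.
#' ROC points are accumulated over the distinct score thresholds.
#'
#' @param labels binary labels; a factor's second level, the label "M",
#'   1, or TRUE is the positive class
#' @param scores numeric classifier scores, larger = more positive
#' @return a list with \code{auc} and \code{points} (a \code{DataFrame}
#'   of fpr, tpr, threshold)
#' @export
rocAuc <- function(labels, scores) {
    if (length(labels) != length(scores))
        stop("labels and scores must have equal length")
    pos <- if (is.factor(labels)) labels == levels(labels)[2]
           else if (is.character(labels)) labels == "M"
           else as.logical(labels)
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) stop("both classes must be present")
    r <- rank(scores)                       # midranks for ties
    auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    ord <- order(scores, decreasing = TRUE)
    thr <- scores[ord]
    keep <- !duplicated(thr)
    tp <- cumsum(pos[ord])[c(which(keep)[-1] - 1L, length(thr))]
    fp <- cumsum(!pos[ord])[c(which(keep)[-1] - 1L, length(thr))]
    points <- DataFrame(
        fpr = c(0, fp / n0), tpr = c(0, tp / n1),
        threshold = c(Inf, thr[keep]))
    list(auc = auc, points = points)
}

#' Per-feature report for the top-ranked features
#'
#' Companion table to a score table: for each of the top \code{n}
#' features, a two-sided two-sample test of M vs C restricted to the
#' reference time point (index 0) and pooled over all time points.
#' Welch's t-test by default; Mann-Whitney as an option. Degenerate
#' strata (constant values) yield NA p-values.
#'
#' @param x the scored \linkS4class{TimeCourseExperiment}
#' @param scores a score table from [wrdaScore()] / [w2rdaScore()]
#' @param n number of top features to report (clipped with a warning)
#' @param test "welch" or "wilcoxon"
#' @return a \code{DataFrame} with rank, score, and p-values \code{pT0}
#'   (reference time point only) and \code{pPooled} (all samples)
#' @export
reportTables <- function(x, scores, n = 30, test = c("welch", "wilcoxon")) {
    test <- match.arg(test)
    stopifnot(is(x, "TimeCourseExperiment"))
    if (n > nrow(scores)) {
        warning(sprintf("n = %d clipped to %d features", n, nrow(scores)))
        n <- nrow(scores)
    }
    ids <- topFeatures(scores, n)
    grp <- sampleGroup(x)
    at0 <- timePoint(x) == 0
    mat <- assay(x, "intensity")
    pOf <- function(v, g) {
        if (length(unique(v[g == "C"])) < 2L && length(unique(v[g == "M"])) < 2L &&
            test == "welch") return(NA_real_)
        tryCatch(
            if (test == "welch") t.test(v[g == "M"], v[g == "C"])$p.value
            else suppressWarnings(
                wilcox.test(v[g == "M"], v[g == "C"])$p.value),
            error = function(e) NA_real_)
    }
    pT0 <- vapply(ids, function(f) pOf(mat[f, at0], grp[at0]), numeric(1))
    pPooled <- vapply(ids, function(f) pOf(mat[f, ], grp), numeric(1))
    DataFrame(rank = scores[ids, "rank"], score = scores[ids, "score"],
              pT0 = pT0, pPooled = pPooled, row.names = ids)
}
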