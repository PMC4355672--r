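.scoresFromStats <- function(st, w, epsilon) {
    dmu <- abs(st$muC - st$muM)
    ssum <- st$sdC + st$sdM
    dmu[is.na(dmu)] <- 0
    ssum[is.na(ssum)] <- 0
    D <- as.vector(dmu %*% w)
    S <- as.vector(ssum %*% w)
    s <- D / (S + epsilon)
    s[D == 0] <- 0
    s
}

## All distinct stratified label assignments of a small dataset: within each
## stratum, every way of choosing which samples carry label C.
.exhaustiveLabels <- function(grp, strataIdx, limit = 100000) {
    combos <- lapply(strataIdx, function(idx) {
        nC <- sum(grp[idx] == "C")
        combn(length(idx), nC, simplify = FALSE)
    })
    total <- prod(lengths(combos))
    if (total > limit)
        stop(sprintf(
            "exhaustive enumeration would need %d permutations (limit %d)",
            total, limit))
    choice <- expand.grid(lapply(combos, seq_along))
    lapply(seq_len(nrow(choice)), function(b) {
        g <- grp
        for (s in seq_along(strataIdx)) {
            idx <- strataIdx[[s]]
            g[idx] <- "M"
            g[idx[combos[[s]][[choice[b, s]]]]] <- "C"
        }
        g
    })
}

#' Permutation null distribution of wRDA / w2RDA scores
#'
#' Recomputes every feature's score under \code{B} random relabelings of
#' the samples. Group labels are shuffled within each (time point,
#' sampling time) stratum so the time design and per-stratum sample
#' counts are preserved; only the group assignment is broken. With
#' \code{exhaustive = TRUE} all distinct stratified assignments are
#' enumerated instead (small designs only), making downstream FDR
#' estimates exact rather than Monte Carlo.
#'
#' @inheritParams w2rdaScore
#' @param x a \linkS4class{TimeCourseExperiment}
#' @param B number of permutations (200 is the conventional default)
#' @param seed RNG seed; results are bit-reproducible given the seed
#' @param exhaustive enumerate every distinct assignment instead of
#'   sampling (caps at 100000 assignments)
#' @return a \linkS4class{PermutationNull}
#' @seealso [fdrAtN()], [lowestFdr()], [noiseFilter()]
#' @export
permuteScores <- function(x, omega, k = NULL, epsilon = 0.005, B = 200,
                          seed = 1, exhaustive = FALSE) {
    stopifnot(is(x, "TimeCourseExperiment"))
    if (!exhaustive && (length(B) != 1L || B < 1L))
        stop("B must be a positive integer")
    str <- .strataOf(x)
    nS <- nrow(str$key)
    w <- .stratumWeights(str$key, omega, k)
    grp <- sampleGroup(x)
    strataIdx <- split(seq_along(grp), str$sidx)
    pure <- vapply(strataIdx, function(idx) length(unique(grp[idx])) == 1L,
                   logical(1))
    if (any(pure))
        message(sprintf(
            "%d stratum/strata carry a single group; permutation is a no-op there",
            sum(pure)))
    mat <- assay(x, "intensity")
    mat2 <- mat^2
    labelSets <- if (exhaustive) {
        .exhaustiveLabels(grp, strataIdx)
    } else {
        set.seed(seed)
        lapply(seq_len(B), function(b) {
            g <- grp
            for (idx in strataIdx)
                g[idx] <- sample(g[idx])
            g
        })
    }
    null <- vapply(labelSets, function(g) {
        .scoresFromStats(.stratumStats(mat, mat2, g, str$sidx, nS), w, epsilon)
    }, numeric(nrow(mat)))
    null <- if (is.matrix(null)) t(null) else matrix(null, ncol = 1L)
    colnames(null) <- rownames(mat)
    new("PermutationNull", nullScores = null, B = nrow(null),
        seed = as.integer(seed), exhaustive = exhaustive)
}

#' @rdname PermutationNull-accessors
#' @title Accessors for PermutationNull objects
#' @param x a \linkS4class{PermutationNull}
#' @export
setMethod("nullScores", "PermutationNull", function(x) x@nullScores)

setMethod("show", "PermutationNull", function(object) {
    cat(sprintf("PermutationNull: %d permutations x %d features%s (seed %d)\n",
                object@B, ncol(object@nullScores),
                if (object@exhaustive) " [exhaustive]" else "",
                object@seed))
})

#' SAM-style FDR estimate at a top-n cut
#'
#' For the n-th largest observed score \eqn{s_{(n)}}, counts how many null
#' scores reach it in each permutation; the FDR estimate is the mean
#' exceedance count divided by n, clipped at 1:
#' \deqn{\widehat{FDR}(n) = \min\!\left(1,\;
#'   \frac{1}{Bn}\sum_b \#\{f : s^0_{b,f} \ge s_{(n)}\}\right).}
#'
#' @param observed a score table from [wrdaScore()] / [w2rdaScore()]
#' @param null a \linkS4class{PermutationNull} computed with the same
#'   weights and epsilon
#' @param n top-n cut, 1 <= n <= number of features
#' @param summary "mean" (default) or "median" exceedance count across
#'   permutations
#' @return the FDR estimate, a number in [0, 1]
#' @export
fdrAtN <- function(observed, null, n, summary = c("mean", "median")) {
    summary <- match.arg(summary)
    F <- nrow(observed)
    if (length(n) != 1L || n < 1L || n > F)
        stop(sprintf("n must lie in [1, %d]", F))
    sn <- sort(observed$score, decreasing = TRUE)[n]
    exceed <- rowSums(nullScores(null) >= sn)
    ev <- if (summary == "mean") mean(exceed) else stats::median(exceed)
    min(1, ev / n)
}

#' FDR estimates over a grid of top-n cuts
#'
#' @inheritParams fdrAtN
#' @param nGrid top-n cuts to evaluate
#' @return a \code{DataFrame} with columns \code{n}, \code{threshold}
#'   (the n-th largest observed score), \code{expectedNull} and \code{fdr}
#' @export
fdrCurve <- function(observed, null, nGrid = c(50, 45, 40, 35, 30),
                     summary = c("mean", "median")) {
    summary <- match.arg(summary)
    if (!length(nGrid)) stop("nGrid must be nonempty")
    sorted <- sort(observed$score, decreasing = TRUE)
    nullM <- nullScores(null)
    rows <- lapply(nGrid, function(n) {
        if (n < 1L || n > length(sorted))
            stop(sprintf("n = %d outside [1, %d]", n, length(sorted)))
        sn <- sorted[n]
        exceed <- rowSums(nullM >= sn)
        ev <- if (summary == "mean") mean(exceed) else stats::median(exceed)
        c(n = n, threshold = sn, expectedNull = ev, fdr = min(1, ev / n))
    })
    m <- do.call(rbind, rows)
    DataFrame(n = as.integer(m[, "n"]), threshold = m[, "threshold"],
              expectedNull = m[, "expectedNull"], fdr = m[, "fdr"])
}

#' Lowest FDR across a grid of top-n cuts
#'
#' The selection criterion of the weight-function grid search: the minimum
#' FDR over the candidate cuts, with ties resolved toward the largest n
#' (the least restrictive cut attaining the minimum).
#'
#' @inheritParams fdrCurve
#' @return a list with elements \code{fdr} (the minimum) and \code{n}
#' @export
lowestFdr <- function(observed, null, nGrid = c(50, 45, 40, 35, 30),
                      summary = c("mean", "median")) {
    crv <- fdrCurve(observed, null, nGrid, summary)
    crv <- crv[order(-crv$n), , drop = FALSE]
    i <- which.min(crv$fdr)
    list(fdr = crv$fdr[i], n = crv$n[i])
}

#' Remove noise features by a pooled permutation-null threshold
#'
#' First-level filtering: a feature is retained only if its observed score
#' exceeds the chosen quantile of the pooled null score distribution, so
#' features whose scores are indistinguishable from label noise are
#' dropped before any weighted re-ranking.
#'
#' @inheritParams fdrAtN
#' @param quantile pooled-null quantile acting as the retention threshold
#' @return retained feature ids, ordered by observed rank
#' @export
noiseFilter <- function(observed, null, quantile = 0.95) {
    if (length(quantile) != 1L || quantile <= 0 || quantile >= 1)
        stop("quantile must lie in (0, 1)")
    thr <- stats::quantile(as.vector(nullScores(null)), probs = quantile,
                           names = FALSE)
    keep <- observed$score > thr
    ids <- rownames(observed)[keep]
    ids[order(observed$rank[keep])]
}
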