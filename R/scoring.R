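## ---- stratum machinery -----------------------------------------------------
## A stratum is one (timePoint, samplingTime) cell; strata are ordered by
## time point then sampling time. All per-permutation work reduces to group
## means / SDs per stratum, computed in one matrix product via a sample ->
## (group, stratum) indicator matrix.

.strataOf <- function(x) {
    tp <- timePoint(x)
    st <- samplingTime(x)
    key <- unique(data.frame(timePoint = tp, samplingTime = st))
    key <- key[order(key$timePoint, key$samplingTime), , drop = FALSE]
    sidx <- match(paste(tp, st), paste(key$timePoint, key$samplingTime))
    list(key = DataFrame(timePoint = as.integer(key$timePoint),
                         samplingTime = as.integer(key$samplingTime)),
         sidx = sidx)
}

## mat: features x samples; mat2 = mat^2 precomputed by callers that loop.
## Returns group means and sample SDs per stratum; absent groups yield NA,
## singleton groups yield sd 0.
.stratumStats <- function(mat, mat2, grp, sidx, nS) {
    n <- ncol(mat)
    ind <- matrix(0, n, 2L * nS)
    ind[cbind(seq_len(n), sidx + (grp == "M") * nS)] <- 1
    cnt <- colSums(ind)
    sums <- mat %*% ind
    mu <- sweep(sums, 2, cnt, "/")          # NaN where a group is absent
    mu[, cnt == 0] <- NA_real_
    ss <- mat2 %*% ind
    varm <- sweep(ss - sweep(mu^2, 2, cnt, "*"), 2, pmax(cnt - 1, 1), "/")
    varm[, cnt <= 1] <- 0
    varm[, cnt == 0] <- NA_real_
    sdm <- sqrt(pmax(varm, 0))
    list(muC = mu[, seq_len(nS), drop = FALSE],
         muM = mu[, nS + seq_len(nS), drop = FALSE],
         sdC = sdm[, seq_len(nS), drop = FALSE],
         sdM = sdm[, nS + seq_len(nS), drop = FALSE],
         nC = as.integer(cnt[seq_len(nS)]),
         nM = as.integer(cnt[nS + seq_len(nS)]))
}

#' Per-stratum group summaries
#'
#' Computes the mean and sample standard deviation (denominator n-1) of
#' every feature for each group in each (time point, sampling time)
#' stratum. Strata where a group contributes a single sample get SD 0
#' with a diagnostic message; strata missing a group entirely carry NA
#' and only become an error if scoring assigns them positive weight.
#'
#' @param x a \linkS4class{TimeCourseExperiment}
#' @param ... unused
#' @return a \linkS4class{GroupSummary}
#' @export
setMethod("groupSummary", "TimeCourseExperiment", function(x, ...) {
    str <- .strataOf(x)
    nS <- nrow(str$key)
    mat <- assay(x, "intensity")
    st <- .stratumStats(mat, mat^2, sampleGroup(x), str$sidx, nS)
    singles <- which(st$nC == 1L | st$nM == 1L)
    if (length(singles))
        message(sprintf(
            "singleton group stratum at (time point, sampling time): %s; SD set to 0",
            paste(sprintf("(%d, %d)", str$key$timePoint[singles],
                          str$key$samplingTime[singles]), collapse = " ")))
    new("GroupSummary", muC = st$muC, muM = st$muM,
        sdC = st$sdC, sdM = st$sdM, nC = st$nC, nM = st$nM,
        strata = str$key)
})

setMethod("show", "GroupSummary", function(object) {
    cat(sprintf("GroupSummary: %d features x %d strata over %d time points\n",
                nrow(object@muC), ncol(object@muC),
                length(unique(object@strata$timePoint))))
})

#' Construct a GroupSummary from explicit statistics
#'
#' Mainly for direct evaluation of the scores from published or hand-built
#' summary statistics; [groupSummary()] derives the same object from data.
#'
#' @param muC,muM features x strata matrices of group means
#' @param sdC,sdM features x strata matrices of group SDs (default 0)
#' @param timePoint,samplingTime per-stratum indices; defaults: strata are
#'   consecutive time points with a single sampling time
#' @param nC,nM per-stratum sample counts (default 1)
#' @return a \linkS4class{GroupSummary}
#' @export
GroupSummary <- function(muC, muM, sdC = 0 * muC, sdM = 0 * muM,
                         timePoint = seq_len(ncol(as.matrix(muC))) - 1L,
                         samplingTime = rep(0L, ncol(as.matrix(muC))),
                         nC = rep(1L, ncol(as.matrix(muC))),
                         nM = rep(1L, ncol(as.matrix(muC)))) {
    asm <- function(m) {
        m <- if (is.matrix(m)) m else matrix(m, nrow = 1)
        storage.mode(m) <- "double"
        m
    }
    new("GroupSummary", muC = asm(muC), muM = asm(muM),
        sdC = asm(sdC), sdM = asm(sdM),
        nC = as.integer(nC), nM = as.integer(nM),
        strata = DataFrame(timePoint = as.integer(timePoint),
                           samplingTime = as.integer(samplingTime)))
}

## Expand (omega over time points, k over sampling times) into one weight
## per stratum: w_s = omega[i_s] * k_i[j_s], with the k vector regenerated
## per time point when the number of sampling times varies.
.stratumWeights <- function(strata, omega, k = NULL) {
    tps <- sort(unique(strata$timePoint))
    N <- length(tps)
    if (length(weightValues(omega)) != N)
        stop(sprintf("omega has length %d but the data have %d time points",
                     length(weightValues(omega)), N))
    ov <- weightValues(omega)
    w <- numeric(nrow(strata))
    for (ii in seq_along(tps)) {
        sel <- which(strata$timePoint == tps[ii])
        p <- length(sel)
        if (is.null(k)) {
            kv <- weightValues(makeWeights("equal", n = p))
        } else if (weightFamily(k) %in% c("explicit", "equal") &&
                   length(weightValues(k)) == p) {
            kv <- weightValues(k)
        } else if (weightFamily(k) == "explicit") {
            stop(sprintf(
                "explicit k has length %d but time point %d has %d sampling times",
                length(weightValues(k)), tps[ii], p))
        } else {
            kv <- weightValues(makeWeights(weightFamily(k),
                                           q = changingFactor(k), n = p,
                                           normalize = k@normalized))
        }
        ord <- order(strata$samplingTime[sel])
        w[sel[ord]] <- ov[ii] * kv
    }
    w
}

## Core score computation shared by wRDA and w2RDA so the p = 1 reduction
## is bit-identical by construction.
.scoreTable <- function(summary, w, epsilon, omega, k) {
    if (epsilon < 0) stop("epsilon must be non-negative")
    dmu <- abs(summary@muC - summary@muM)
    ssum <- summary@sdC + summary@sdM
    if (any(w > 0)) {
        bad <- which(colSums(is.na(dmu[, w > 0, drop = FALSE])) > 0)
        if (length(bad)) {
            pos <- which(w > 0)[bad[1]]
            stop(sprintf(
                "stratum (time point %d, sampling time %d) has positive weight but lacks a group",
                summary@strata$timePoint[pos], summary@strata$samplingTime[pos]))
        }
    }
    dmu[is.na(dmu)] <- 0
    ssum[is.na(ssum)] <- 0
    D <- as.vector(dmu %*% w)
    S <- as.vector(ssum %*% w)
    score <- D / (S + epsilon)
    score[D == 0] <- 0                      # covers epsilon = 0 with S = 0
    ord <- order(-score)                    # stable: ties keep input order
    rank <- integer(length(score))
    rank[ord] <- seq_along(score)
    ids <- rownames(summary@muC)
    if (is.null(ids)) ids <- paste0("F", seq_along(score))
    out <- DataFrame(D = D, S = S, score = score, rank = rank,
                     row.names = ids)
    metadata(out) <- list(epsilon = epsilon, omega = omega, k = k,
                          stratumWeights = w)
    out
}

#' wRDA and w2RDA feature scores
#'
#' Scores every feature's ability to discriminate the two groups over the
#' whole time course. The weighted relative difference accumulation of a
#' feature f is
#' \deqn{D(f) = \sum_i \omega_i\,|\mu_{C,f}(i) - \mu_{M,f}(i)|, \quad
#'       S(f) = \sum_i \omega_i\,(\sigma_{C,f}(i) + \sigma_{M,f}(i)),}
#' \deqn{\mathrm{wRDA}(f) = D(f) / (S(f) + \epsilon),}
#' a SAM-style relative difference accumulated along the time axis: the
#' weighted between-group mean separation relative to the weighted
#' within-group scatter, with \eqn{\epsilon} a small regularizer guarding
#' against near-zero accumulated SDs (default 0.005).
#'
#' \code{w2rdaScore} extends this to designs where each time point was
#' sampled in several batches (sampling times) by adding a second weight
#' layer k over the batches within every time point:
#' \eqn{D(f) = \sum_i \omega_i \sum_j k_j |\mu_{C,f}(i,j) - \mu_{M,f}(i,j)|}
#' and analogously for S. With a single sampling time per point and
#' k = (1) it reduces exactly to \code{wrdaScore}.
#'
#' @param x a \linkS4class{TimeCourseExperiment} or a
#'   \linkS4class{GroupSummary}
#' @param omega a \linkS4class{WeightScheme} over the N time points
#' @param k a \linkS4class{WeightScheme} over sampling times, regenerated
#'   per time point from its (family, q) when the number of sampling
#'   times varies; \code{NULL} = equal weights
#' @param epsilon non-negative regularizer in the denominator
#' @param ... unused
#' @return a score table: a \code{DataFrame} with one row per feature and
#'   columns \code{D}, \code{S}, \code{score}, \code{rank} (1 = best), with
#'   the epsilon and weight schemes in \code{metadata()}
#' @examples
#' gs <- GroupSummary(muC = rbind(c(1, 2)), muM = rbind(c(3, 1)),
#'                    sdC = rbind(c(1, 1)), sdM = rbind(c(1, 1)))
#' wrdaScore(gs, explicitWeights(c(0.25, 0.75)), epsilon = 0)$score  # 0.625
#' @rdname wrdaScore
#' @export
setMethod("wrdaScore", "TimeCourseExperiment",
          function(x, omega, epsilon = 0.005, ...) {
    if (any(samplingTime(x) != 0))
        stop("wrdaScore expects one sampling time per time point; use w2rdaScore")
    wrdaScore(suppressMessages(groupSummary(x)), omega, epsilon = epsilon)
})

#' @rdname wrdaScore
#' @export
setMethod("wrdaScore", "GroupSummary",
          function(x, omega, epsilon = 0.005, ...) {
    if (any(x@strata$samplingTime != 0))
        stop("wrdaScore expects one sampling time per time point; use w2rdaScore")
    w <- .stratumWeights(x@strata, omega, k = NULL)
    .scoreTable(x, w, epsilon, omega, NULL)
})

#' @rdname wrdaScore
#' @export
setMethod("w2rdaScore", "TimeCourseExperiment",
          function(x, omega, k = NULL, epsilon = 0.005, ...) {
    w2rdaScore(suppressMessages(groupSummary(x)), omega, k = k,
               epsilon = epsilon)
})

#' @rdname wrdaScore
#' @export
setMethod("w2rdaScore", "GroupSummary",
          function(x, omega, k = NULL, epsilon = 0.005, ...) {
    w <- .stratumWeights(x@strata, omega, k = k)
    .scoreTable(x, w, epsilon, omega, k)
})

#' Top-ranked features of a score table
#'
#' @param scores a score table from [wrdaScore()] / [w2rdaScore()]
#' @param n how many features (1 <= n <= number of features)
#' @return feature ids in rank order
#' @export
topFeatures <- function(scores, n) {
    F <- nrow(scores)
    if (length(n) != 1L || n < 1L || n > F)
        stop(sprintf("n must lie in [1, %d]", F))
    rownames(scores)[order(scores$rank)][seq_len(n)]
}
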