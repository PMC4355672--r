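.scoresMatrixFromStats <- function(st, W, epsilon) {
    dmu <- abs(st$muC - st$muM)
    ssum <- st$sdC + st$sdM
    dmu[is.na(dmu)] <- 0
    ssum[is.na(ssum)] <- 0
    D <- dmu %*% W
    S <- ssum %*% W
    sc <- D / (S + epsilon)
    sc[D == 0] <- 0
    sc
}

## One row per weight-scheme cell along one axis: equal is a single q-less
## cell (stored with q = 0, to which every parametric family collapses).
.axisCells <- function(families, qGrid) {
    fam <- character(0); q <- numeric(0)
    for (f in families) {
        if (f == "equal") {
            fam <- c(fam, "equal"); q <- c(q, 0)
        } else {
            fam <- c(fam, rep(f, length(qGrid))); q <- c(q, qGrid)
        }
    }
    data.frame(family = fam, q = q)
}

.schemeFor <- function(family, q, n, normalize = TRUE) {
    if (family == "equal") makeWeights("equal", n = n, normalize = normalize)
    else makeWeights(family, q = q, n = n, normalize = normalize)
}

#' Grid search over weight-function settings by lowest permutation FDR
#'
#' Evaluates every combination of sampling-time weight setting
#' (k family, q_k) and time-point weight setting (omega family, q_omega),
#' scoring the data with w2RDA under each pair and estimating the lowest
#' FDR over the top-n grid from a stratified permutation null. One
#' permutation stream (derived from \code{seed}) is shared by all cells,
#' so cells are compared against identical relabelings and the whole
#' table is reproducible from the single seed.
#'
#' @inheritParams permuteScores
#' @param families weight families to scan on both axes; \code{"equal"}
#'   contributes a single q-less cell
#' @param qGrid changing factors for the parametric families
#'   (default 0.1 to 1.0 in steps of 0.1)
#' @param nGrid top-n cuts for the FDR curve
#' @param normalize normalize each generated weight vector to sum 1
#' @return a \linkS4class{GridResult}
#' @seealso [selectWeights()], [familyPreference()]
#' @export
gridSearch <- function(x,
                       families = c("equal", "linear", "exponential",
                                    "proportional"),
                       qGrid = seq(0.1, 1.0, by = 0.1),
                       nGrid = c(50, 45, 40, 35, 30),
                       epsilon = 0.005, B = 200, seed = 1,
                       normalize = TRUE) {
    stopifnot(is(x, "TimeCourseExperiment"))
    if (!length(families) || !length(nGrid))
        stop("families and nGrid must be nonempty")
    F <- nrow(x)
    if (any(nGrid < 1L) || any(nGrid > F))
        stop(sprintf("nGrid entries must lie in [1, %d]", F))
    nGrid <- sort(unique(as.integer(nGrid)), decreasing = TRUE)
    str <- .strataOf(x)
    nS <- nrow(str$key)
    N <- length(unique(str$key$timePoint))
    kAxis <- .axisCells(families, qGrid)
    wAxis <- kAxis
    cells <- expand.grid(kCell = seq_len(nrow(kAxis)),
                         wCell = seq_len(nrow(wAxis)))
    W <- matrix(0, nS, nrow(cells))
    for (c_ in seq_len(nrow(cells))) {
        kc <- kAxis[cells$kCell[c_], ]
        wc <- wAxis[cells$wCell[c_], ]
        omega <- .schemeFor(wc$family, wc$q, N, normalize)
        kScheme <- .schemeFor(kc$family, kc$q,
                              max(str$key$samplingTime) + 1L, normalize)
        W[, c_] <- .stratumWeights(str$key, omega, kScheme)
    }
    grp <- sampleGroup(x)
    mat <- assay(x, "intensity")
    mat2 <- mat^2
    obsStats <- .stratumStats(mat, mat2, grp, str$sidx, nS)
    obs <- .scoresMatrixFromStats(obsStats, W, epsilon)
    thr <- apply(obs, 2, function(s) sort(s, decreasing = TRUE)[nGrid])
    thr <- matrix(thr, nrow = length(nGrid))
    strataIdx <- split(seq_along(grp), str$sidx)
    exceed <- matrix(0, length(nGrid), nrow(cells))
    set.seed(seed)
    for (b in seq_len(B)) {
        g <- grp
        for (idx in strataIdx)
            g[idx] <- sample(g[idx])
        nullSc <- .scoresMatrixFromStats(
            .stratumStats(mat, mat2, g, str$sidx, nS), W, epsilon)
        for (t_ in seq_along(nGrid))
            exceed[t_, ] <- exceed[t_, ] +
                colSums(nullSc >= matrix(thr[t_, ], F, nrow(cells),
                                         byrow = TRUE))
    }
    fdr <- sweep(exceed / B, 1, nGrid, "/")
    fdr[fdr > 1] <- 1
    bestIdx <- apply(fdr, 2, which.min)      # nGrid sorted decreasing:
    lowest <- fdr[cbind(bestIdx, seq_len(ncol(fdr)))]  # ties -> largest n
    tab <- DataFrame(
        kFamily = kAxis$family[cells$kCell],
        kQ = kAxis$q[cells$kCell],
        omegaFamily = wAxis$family[cells$wCell],
        omegaQ = wAxis$q[cells$wCell],
        lowestFdr = lowest,
        bestN = nGrid[bestIdx])
    new("GridResult", table = tab, nGrid = nGrid,
        nTimePoints = as.integer(N),
        samplingTimes = .samplingTimesPerPoint(x))
}

#' @rdname GridResult-accessors
#' @title Accessors for GridResult objects
#' @param x a \linkS4class{GridResult}
#' @export
setMethod("gridTable", "GridResult", function(x) x@table)

setMethod("show", "GridResult", function(object) {
    cat(sprintf("GridResult: %d cells, top-n grid {%s}\n",
                nrow(object@table), paste(object@nGrid, collapse = ", ")))
    sel <- selectWeights(object)
    cat(sprintf("  selected: k = %s (q = %g), omega = %s (q = %g), lowest FDR %.4g at n = %d\n",
                sel$kFamily, sel$kQ, sel$omegaFamily, sel$omegaQ,
                sel$lowestFdr, sel$bestN))
})

#' Construct a GridResult from an explicit cell table
#'
#' Mostly useful for exercising the selection rules on hand-built tables;
#' [gridSearch()] produces the same object from data.
#'
#' @param table a data.frame or DataFrame with columns kFamily, kQ,
#'   omegaFamily, omegaQ, lowestFdr, bestN
#' @param nGrid,nTimePoints,samplingTimes optional design metadata
#' @return a \linkS4class{GridResult}
#' @export
GridResult <- function(table, nGrid = integer(0), nTimePoints = integer(0),
                       samplingTimes = integer(0)) {
    new("GridResult", table = as(table, "DataFrame"),
        nGrid = as.integer(nGrid), nTimePoints = as.integer(nTimePoints),
        samplingTimes = as.integer(samplingTimes))
}

#' Select the weight settings from a grid-search result
#'
#' Among the cells attaining the minimal lowest-FDR: (1) restrict to the
#' (k family, omega family) pair contributing the most tied cells, (2)
#' take the smallest changing factor q_k — minimizing the weight
#' differences among sampling times — and (3) with k fixed, the smallest
#' q_omega. The order (k before omega) is deliberate: the sampling-time
#' layer is resolved first.
#'
#' @param result a \linkS4class{GridResult}
#' @return a list with the selected \code{kFamily}, \code{kQ},
#'   \code{omegaFamily}, \code{omegaQ}, \code{lowestFdr}, \code{bestN},
#'   and — when the design dimensions are recorded — ready-made
#'   \code{omega} and \code{k} \linkS4class{WeightScheme}s
#' @export
selectWeights <- function(result) {
    stopifnot(is(result, "GridResult"))
    tab <- as.data.frame(result@table)
    if (!nrow(tab)) stop("empty grid result")
    cand <- tab[tab$lowestFdr == min(tab$lowestFdr), , drop = FALSE]
    pair <- paste(cand$kFamily, cand$omegaFamily, sep = "/")
    counts <- table(pair)
    cand <- cand[pair %in% names(counts)[counts == max(counts)], ,
                 drop = FALSE]
    cand <- cand[order(cand$kQ, cand$omegaQ), , drop = FALSE]
    sel <- cand[1, ]
    out <- list(kFamily = sel$kFamily, kQ = sel$kQ,
                omegaFamily = sel$omegaFamily, omegaQ = sel$omegaQ,
                lowestFdr = sel$lowestFdr, bestN = sel$bestN,
                omega = NULL, k = NULL)
    if (length(result@nTimePoints) == 1L)
        out$omega <- .schemeFor(sel$omegaFamily, sel$omegaQ,
                                result@nTimePoints)
    if (length(result@samplingTimes))
        out$k <- .schemeFor(sel$kFamily, sel$kQ,
                            max(result@samplingTimes))
    out
}

#' Frequency of weight-family pairs among low-FDR grid cells
#'
#' Tallies which (k family, omega family) pairs most often reach an FDR
#' below the ceiling — evidence for which functional form suits the data,
#' independent of the single selected cell.
#'
#' @param result a \linkS4class{GridResult}
#' @param fdrCeiling qualification threshold (default 0.05)
#' @return a \code{DataFrame} with columns kFamily, omegaFamily, count,
#'   fraction, sorted by count; zero rows if no cell qualifies
#' @export
familyPreference <- function(result, fdrCeiling = 0.05) {
    stopifnot(is(result, "GridResult"))
    tab <- as.data.frame(result@table)
    qual <- tab[tab$lowestFdr < fdrCeiling, , drop = FALSE]
    if (!nrow(qual))
        return(DataFrame(kFamily = character(0), omegaFamily = character(0),
                         count = integer(0), fraction = numeric(0)))
    agg <- stats::aggregate(list(count = rep(1L, nrow(qual))),
                            by = list(kFamily = qual$kFamily,
                                      omegaFamily = qual$omegaFamily),
                            FUN = sum)
    agg <- agg[order(-agg$count, agg$kFamily, agg$omegaFamily), ]
    DataFrame(kFamily = agg$kFamily, omegaFamily = agg$omegaFamily,
              count = as.integer(agg$count),
              fraction = agg$count / nrow(qual))
}
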