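#' Remove features unreliably detected (zero-inflated) in any stratum
#'
#' A feature is removed when, within at least one (group, time point)
#' stratum, the fraction of zero intensities strictly exceeds
#' \code{maxZeroFrac} ("more than 20\%" by default — exactly 20\% is
#' retained). Zeros in LC-MS feature tables mark non-detection, so a
#' feature failing this rule cannot be summarized reliably at that stage.
#' Retained features keep their original order. The removal report is
#' stored in \code{metadata(.)$zeroFilter}.
#'
#' @param x a \linkS4class{TimeCourseExperiment}
#' @param maxZeroFrac tolerated zero fraction per stratum, in [0, 1]
#' @return the filtered \linkS4class{TimeCourseExperiment}
#' @export
zeroFilter <- function(x, maxZeroFrac = 0.2) {
    stopifnot(is(x, "TimeCourseExperiment"))
    if (length(maxZeroFrac) != 1L || maxZeroFrac < 0 || maxZeroFrac > 1)
        stop("maxZeroFrac must lie in [0, 1]")
    mat <- assay(x, "intensity")
    key <- paste(sampleGroup(x), timePoint(x))
    remove <- rep(FALSE, nrow(mat))
    for (k in unique(key)) {
        sub <- mat[, key == k, drop = FALSE]
        remove <- remove | (rowMeans(sub == 0) > maxZeroFrac)
    }
    out <- x[!remove, ]
    metadata(out)$zeroFilter <- list(
        removed = rownames(mat)[remove],
        maxZeroFrac = maxZeroFrac)
    out
}

## Rejection-sample one replacement from Normal(m, s) truncated to
## [lo, hi]; falls back to m (always inside) if acceptance is too rare.
.drawInRange <- function(m, s, lo, hi, maxTries = 10000L) {
    for (tries in seq_len(maxTries)) {
        v <- rnorm(1L, m, s)
        if (v >= lo && v <= hi) return(v)
    }
    m
}

#' Correct outlier intensities by sigma-range screening
#'
#' Within each (group, time point) stratum of every feature, a value is
#' an outlier when it falls outside \eqn{\mu \pm k\sigma}, with \eqn{\mu}
#' and \eqn{\sigma} the stratum mean and SD computed over all values
#' (outliers included). Each outlier is replaced by a draw from a normal
#' distribution fitted to the stratum's non-outlier values, redrawn until
#' it lies inside the acceptance range; non-outliers are untouched.
#' Deterministic given \code{seed}. Strata with fewer than two samples
#' are skipped with a diagnostic. The correction report (one row per
#' replaced cell) is stored in \code{metadata(.)$outlierCorrect}.
#'
#' @param x a \linkS4class{TimeCourseExperiment}
#' @param kSigma the range half-width in SD units (default 2)
#' @param seed RNG seed for the replacement draws
#' @return the corrected \linkS4class{TimeCourseExperiment}
#' @export
outlierCorrect <- function(x, kSigma = 2.0, seed = 1) {
    stopifnot(is(x, "TimeCourseExperiment"))
    if (length(kSigma) != 1L || kSigma <= 0)
        stop("kSigma must be positive")
    set.seed(seed)
    mat <- assay(x, "intensity")
    key <- paste(sampleGroup(x), timePoint(x))
    cells <- list()
    skipped <- character(0)
    for (k in unique(key)) {
        idx <- which(key == k)
        if (length(idx) < 2L) {
            skipped <- c(skipped, k)
            next
        }
        sub <- mat[, idx, drop = FALSE]
        mu <- rowMeans(sub)
        sigma <- sqrt(rowSums((sub - mu)^2) / (ncol(sub) - 1L))
        lo <- mu - kSigma * sigma
        hi <- mu + kSigma * sigma
        flag <- sub < lo | sub > hi
        for (f in which(rowSums(flag) > 0)) {
            inner <- sub[f, !flag[f, ]]
            m <- mean(inner)
            s <- if (length(inner) > 1L) sd(inner) else 0
            for (col in which(flag[f, ])) {
                old <- sub[f, col]
                newv <- .drawInRange(m, s, lo[f], hi[f])
                mat[f, idx[col]] <- newv
                cells[[length(cells) + 1L]] <- data.frame(
                    sample = colnames(mat)[idx[col]],
                    feature = rownames(mat)[f],
                    old = old, new = newv)
            }
        }
    }
    if (length(skipped))
        message(sprintf(
            "stratum/strata skipped (fewer than 2 samples): %s",
            paste(skipped, collapse = "; ")))
    out <- x
    assay(out, "intensity") <- mat
    metadata(out)$outlierCorrect <- list(
        cells = if (length(cells)) do.call(rbind, cells)
                else data.frame(sample = character(0),
                                feature = character(0),
                                old = numeric(0), new = numeric(0)),
        kSigma = kSigma, seed = seed, skippedStrata = skipped)
    out
}
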