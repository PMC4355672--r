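#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom stats rnorm runif sd quantile t.test wilcox.test predict
#' @importFrom utils read.csv read.delim write.table combn
NULL

WEIGHT_FAMILIES <- c("equal", "linear", "proportional", "exponential", "explicit")

#' Container for two-group time-course feature tables
#'
#' A thin \linkS4class{SummarizedExperiment} subclass for two-group
#' (control \code{C} vs model \code{M}) time-series metabolomics data.
#' Features are rows of the single \code{"intensity"} assay; per-sample
#' metadata in \code{colData} carries the group label, the 0-based time
#' point index \code{timePoint} (index 0 is the reference stage, e.g. the
#' diagnosis stage in a prospective cohort design) and the 0-based
#' sampling-time index \code{samplingTime} within each time point (always
#' 0 when each time point was sampled in a single batch).
#'
#' @seealso [TimeCourseExperiment()], [validateTimeCourse()]
#' @aliases TimeCourseExperiment-class
#' @exportClass TimeCourseExperiment
setClass("TimeCourseExperiment", contains = "SummarizedExperiment")

setValidity("TimeCourseExperiment", function(object) {
    cd <- colData(object)
    needed <- c("group", "timePoint", "samplingTime")
    missing <- setdiff(needed, colnames(cd))
    if (length(missing))
        return(sprintf("colData lacks column(s): %s",
                       paste(missing, collapse = ", ")))
    if (!all(as.character(cd$group) %in% c("C", "M")))
        return("group labels must be 'C' or 'M'")
    tp <- cd$timePoint
    st <- cd$samplingTime
    if (!is.numeric(tp) || any(tp != as.integer(tp)) || any(tp < 0))
        return("timePoint must hold non-negative integers")
    if (!is.numeric(st) || any(st != as.integer(st)) || any(st < 0))
        return("samplingTime must hold non-negative integers")
    if (!"intensity" %in% assayNames(object))
        return("assay 'intensity' is required")
    a <- assay(object, "intensity")
    if (!is.numeric(a))
        return("intensity assay must be numeric")
    if (anyNA(a))
        return("intensity assay contains missing values")
    TRUE
})

#' Weight vector over time points or sampling times
#'
#' Wraps a non-negative weight vector together with the generating family
#' and its changing factor \code{q}. The three parametric families give
#' index 0 the largest weight: linear \eqn{1 + (N-i-1)q}, proportional
#' \eqn{(1+q)^{N-i-1}}, exponential \eqn{e^{(N-i-1)q}}. \code{equal} is
#' the constant vector; \code{explicit} wraps a user-supplied vector.
#'
#' @slot family one of equal, linear, proportional, exponential, explicit
#' @slot q changing factor (steepness); \code{NA} for equal/explicit
#' @slot values the weight vector
#' @slot normalized whether \code{values} sum to 1
#' @aliases WeightScheme-class
#' @seealso [makeWeights()], [explicitWeights()]
#' @exportClass WeightScheme
setClass("WeightScheme",
    representation(family = "character", q = "numeric",
                   values = "numeric", normalized = "logical"))

setValidity("WeightScheme", function(object) {
    if (length(object@family) != 1L || !object@family %in% WEIGHT_FAMILIES)
        return(sprintf("family must be one of %s",
                       paste(WEIGHT_FAMILIES, collapse = ", ")))
    v <- object@values
    if (length(v) < 1L) return("at least one weight is required")
    if (any(!is.finite(v)) || any(v < 0))
        return("weights must be finite and non-negative")
    if (all(v == 0)) return("at least one weight must be positive")
    if (isTRUE(object@normalized) && abs(sum(v) - 1) > 1e-12)
        return("normalized weights must sum to 1")
    q <- object@q
    if (object@family %in% c("linear", "proportional", "exponential")) {
        if (!isTRUE(is.finite(q)) || q < 0)
            return("q must be a non-negative number for parametric families")
        if (q > 0 && length(v) > 1L && any(diff(v) >= 0))
            return("parametric weights with q > 0 must strictly decrease")
    }
    TRUE
})

#' Per-stratum group summary statistics
#'
#' Means and sample standard deviations of every feature in each
#' \code{(group, timePoint, samplingTime)} stratum, the building blocks of
#' the wRDA / w2RDA scores. Strata missing one group carry \code{NA}
#' there; scoring errors only if such a stratum receives positive weight.
#'
#' @slot muC,muM features x strata mean matrices for groups C and M
#' @slot sdC,sdM features x strata sample-SD matrices (0 for singletons)
#' @slot nC,nM per-stratum sample counts
#' @slot strata DataFrame with columns \code{timePoint}, \code{samplingTime}
#' @aliases GroupSummary-class
#' @seealso [groupSummary()]
#' @exportClass GroupSummary
setClass("GroupSummary",
    representation(muC = "matrix", muM = "matrix",
                   sdC = "matrix", sdM = "matrix",
                   nC = "integer", nM = "integer",
                   strata = "DataFrame"))

setValidity("GroupSummary", function(object) {
    dims <- vapply(list(object@muC, object@muM, object@sdC, object@sdM),
                   dim, integer(2))
    if (any(dims != dims[, 1]))
        return("mu/sd matrices must share dimensions")
    nS <- ncol(object@muC)
    if (nrow(object@strata) != nS)
        return("strata table must have one row per summary column")
    if (length(object@nC) != nS || length(object@nM) != nS)
        return("sample counts must have one entry per stratum")
    if (any(object@sdC < 0, na.rm = TRUE) || any(object@sdM < 0, na.rm = TRUE))
        return("standard deviations must be non-negative")
    TRUE
})

#' Permutation null distribution of feature scores
#'
#' Scores of every feature recomputed under \code{B} label permutations,
#' shuffled within each \code{(timePoint, samplingTime)} stratum so the
#' time design is preserved. Basis of the SAM-style FDR estimates and of
#' the noise filter.
#'
#' @slot nullScores B x features matrix of permuted scores
#' @slot B number of permutations
#' @slot seed RNG seed used
#' @slot exhaustive whether all distinct stratified assignments were
#'   enumerated instead of sampled
#' @aliases PermutationNull-class
#' @seealso [permuteScores()], [fdrAtN()], [noiseFilter()]
#' @exportClass PermutationNull
setClass("PermutationNull",
    representation(nullScores = "matrix", B = "integer",
                   seed = "integer", exhaustive = "logical"))

setValidity("PermutationNull", function(object) {
    if (nrow(object@nullScores) != object@B)
        return("nullScores must have B rows")
    if (any(object@nullScores < 0, na.rm = TRUE))
        return("null scores must be non-negative")
    TRUE
})

#' Weight-function grid-search result
#'
#' One row per \code{(k family, q_k, omega family, q_omega)} grid cell with
#' the lowest FDR over the top-n grid and the n attaining it.
#'
#' @slot table DataFrame with columns kFamily, kQ, omegaFamily, omegaQ,
#'   lowestFdr, bestN
#' @slot nGrid top-n cuts evaluated
#' @slot nTimePoints number of time points (length of omega), if known
#' @slot samplingTimes sampling times per time point, if known
#' @aliases GridResult-class
#' @seealso [gridSearch()], [selectWeights()], [familyPreference()]
#' @exportClass GridResult
setClass("GridResult",
    representation(table = "DataFrame", nGrid = "integer",
                   nTimePoints = "integer", samplingTimes = "integer"))

setValidity("GridResult", function(object) {
    needed <- c("kFamily", "kQ", "omegaFamily", "omegaQ", "lowestFdr", "bestN")
    missing <- setdiff(needed, colnames(object@table))
    if (length(missing))
        return(sprintf("grid table lacks column(s): %s",
                       paste(missing, collapse = ", ")))
    TRUE
})

#' Specification of a synthetic two-group time-course experiment
#'
#' Describes the geometry (time points, sampling times, samples per
#' stratum), the baseline intensity distribution, the planted
#' group-divergence signal and the contamination (zero inflation,
#' outlier spikes) of a simulated LC-MS style feature table.
#'
#' @slot nFeatures number of features
#' @slot nSignal number of planted discriminative features
#' @slot nTimePoints number of time points N
#' @slot samplingTimes integer vector p_i of sampling times per time point
#' @slot samplesC,samplesM samples per (group, time point, sampling time)
#' @slot baselineMean,baselineSD centre and spread of per-feature baselines
#' @slot delta effect size in units of the per-feature SD
#' @slot profile divergence shape: step, ramp or expdecay (from index 0)
#' @slot onset first diverging time point for step/ramp profiles
#' @slot decayRate decay constant of the expdecay profile
#' @slot storageDecay multiplicative attenuation per sampling-time index
#' @slot zeroRate,outlierRate per-cell contamination probabilities
#' @slot outlierFactor multiplicative magnitude of injected outliers
#' @aliases SimulationSpec-class
#' @seealso [simulationSpec()], [simulateTimeCourse()]
#' @exportClass SimulationSpec
setClass("SimulationSpec",
    representation(nFeatures = "integer", nSignal = "integer",
                   nTimePoints = "integer", samplingTimes = "integer",
                   samplesC = "integer", samplesM = "integer",
                   baselineMean = "numeric", baselineSD = "numeric",
                   delta = "numeric", profile = "character",
                   onset = "integer", decayRate = "numeric",
                   storageDecay = "numeric", zeroRate = "numeric",
                   outlierRate = "numeric", outlierFactor = "numeric"))

setValidity("SimulationSpec", function(object) {
    if (object@nFeatures < 1L) return("nFeatures must be >= 1")
    if (object@nSignal < 0L || object@nSignal > object@nFeatures)
        return("nSignal must lie in [0, nFeatures]")
    if (object@nTimePoints < 2L) return("at least two time points required")
    if (length(object@samplingTimes) != object@nTimePoints ||
        any(object@samplingTimes < 1L))
        return("samplingTimes must give p_i >= 1 for every time point")
    if (object@samplesC < 1L || object@samplesM < 1L)
        return("each stratum needs at least one sample per group")
    if (object@delta < 0) return("delta must be non-negative")
    if (!object@profile %in% c("step", "ramp", "expdecay"))
        return("profile must be step, ramp or expdecay")
    for (r in c(object@zeroRate, object@outlierRate))
        if (r < 0 || r > 1) return("rates must lie in [0, 1]")
    if (object@storageDecay <= 0 || object@storageDecay > 1)
        return("storageDecay must lie in (0, 1]")
    TRUE
})
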