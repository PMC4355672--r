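#' Build a simulation specification
#'
#' Describes a synthetic two-group time-course feature table with the
#' statistical structure the scoring model assumes: per-feature Gaussian
#' baselines shared by both groups, a planted additive group divergence
#' on \code{nSignal} features whose size is \code{delta} per-feature SDs
#' shaped along the time axis by \code{profile}, attenuation across
#' sampling times by \code{storageDecay}, and optional zero inflation
#' (instrument dropouts) and multiplicative outlier spikes.
#'
#' Divergence profiles over time points i = 0..N-1:
#' \describe{
#'   \item{step}{0 before \code{onset}, 1 from \code{onset} on — an
#'     abrupt disease transition}
#'   \item{ramp}{linear rise from 0 at \code{onset} to 1 at N-1}
#'   \item{expdecay}{\eqn{e^{-\lambda i}} with \eqn{\lambda} =
#'     \code{decayRate} — divergence largest at the reference stage
#'     (index 0) and fading backwards in time, the prospective-cohort
#'     geometry}
#' }
#'
#' @param nFeatures,nSignal total and planted-signal feature counts
#' @param nTimePoints number of time points N
#' @param samplingTimes sampling times per time point (scalar recycled)
#' @param samplesC,samplesM samples per (group, time point, sampling time)
#' @param baselineMean,baselineSD centre and SD scale of feature baselines
#' @param delta effect size in per-feature SD units
#' @param profile "step", "ramp" or "expdecay"
#' @param onset first diverging time point (step/ramp)
#' @param decayRate decay constant of "expdecay"
#' @param storageDecay per-sampling-time attenuation factor in (0, 1]
#' @param zeroRate,outlierRate per-cell contamination probabilities
#' @param outlierFactor multiplicative size of injected outliers
#' @return a \linkS4class{SimulationSpec}
#' @seealso [simulateTimeCourse()], [ratDefaultSpec()], [cohortDefaultSpec()]
#' @export
simulationSpec <- function(nFeatures = 1000, nSignal = 30, nTimePoints = 8,
                           samplingTimes = 1, samplesC = 10, samplesM = 10,
                           baselineMean = 1000, baselineSD = 100,
                           delta = 1.5, profile = "step", onset = 4,
                           decayRate = 0.5, storageDecay = 1,
                           zeroRate = 0, outlierRate = 0,
                           outlierFactor = 5) {
    new("SimulationSpec",
        nFeatures = as.integer(nFeatures), nSignal = as.integer(nSignal),
        nTimePoints = as.integer(nTimePoints),
        samplingTimes = rep_len(as.integer(samplingTimes),
                                as.integer(nTimePoints)),
        samplesC = as.integer(samplesC), samplesM = as.integer(samplesM),
        baselineMean = baselineMean, baselineSD = baselineSD,
        delta = delta, profile = profile, onset = as.integer(onset),
        decayRate = decayRate, storageDecay = storageDecay,
        zeroRate = zeroRate, outlierRate = outlierRate,
        outlierFactor = outlierFactor)
}

#' Preset emulating an 8-time-point animal-model design
#'
#' Eight time points sampled in a single batch each (p_i = 1), 10 samples
#' per group per point, 1000 features of which 30 diverge by 1.5 SD in a
#' step starting at the 5th time point (index 4) — a chemically induced
#' disease model monitored from a healthy baseline into late disease.
#'
#' @param ... overrides passed to [simulationSpec()]
#' @return a \linkS4class{SimulationSpec}
#' @export
ratDefaultSpec <- function(...) {
    args <- list(nFeatures = 1000, nSignal = 30, nTimePoints = 8,
                 samplingTimes = 1, samplesC = 10, samplesM = 10,
                 delta = 1.5, profile = "step", onset = 4)
    over <- list(...)
    args[names(over)] <- over
    do.call(simulationSpec, args)
}

#' Preset emulating a 5-stage, 4-sampling-time prospective cohort design
#'
#' Five stages (index 0 = the diagnosis stage) each screened at four
#' calendar sampling times, with few cases (3 per stratum) against twice
#' as many matched controls. The divergence decays exponentially with
#' distance from the diagnosis stage and is attenuated by 0.8 per
#' additional sampling time (longer sample storage); mild zero inflation
#' reflects real screening data.
#'
#' @param ... overrides passed to [simulationSpec()]
#' @return a \linkS4class{SimulationSpec}
#' @export
cohortDefaultSpec <- function(...) {
    args <- list(nFeatures = 1000, nSignal = 30, nTimePoints = 5,
                 samplingTimes = 4, samplesC = 6, samplesM = 3,
                 delta = 1.5, profile = "expdecay", decayRate = 0.5,
                 storageDecay = 0.8, zeroRate = 0.02)
    over <- list(...)
    args[names(over)] <- over
    do.call(simulationSpec, args)
}

.divergenceProfile <- function(spec) {
    i <- seq_len(spec@nTimePoints) - 1L
    switch(spec@profile,
        step = as.numeric(i >= spec@onset),
        ramp = pmax(0, pmin(1, (i - spec@onset + 1) /
                               max(1, spec@nTimePoints - spec@onset))),
        expdecay = exp(-spec@decayRate * i))
}

#' Simulate a two-group time-course dataset with planted signal
#'
#' Control values are drawn as Normal(baseline_f, sd_f) with per-feature
#' baselines spread around \code{baselineMean}; model-group values of the
#' planted signal features are shifted upward by
#' \code{delta * sd_f * profile(i) * storageDecay^j}. Zero inflation is
#' applied before outlier injection (dropouts happen at acquisition,
#' spikes on top of observed values); all intensities are truncated at 0.
#' Deterministic given \code{seed}.
#'
#' @param spec a \linkS4class{SimulationSpec}
#' @param seed RNG seed
#' @return a list with \code{dataset} (a
#'   \linkS4class{TimeCourseExperiment}) and \code{truth} (a list:
#'   \code{signalFeatures}, the planted ids; \code{profile}, the
#'   divergence weight per time point; \code{storageDecay})
#' @examples
#' sim <- simulateTimeCourse(ratDefaultSpec(nFeatures = 50, nSignal = 5),
#'                           seed = 7)
#' validateTimeCourse(sim$dataset)   # character(0)
#' @export
simulateTimeCourse <- function(spec, seed = 1) {
    stopifnot(is(spec, "SimulationSpec"))
    validObject(spec)
    set.seed(seed)
    F <- spec@nFeatures
    featureIds <- sprintf("F%04d", seq_len(F))
    signal <- sort(sample.int(F, spec@nSignal))
    baseline <- spec@baselineMean * runif(F, 0.5, 1.5)
    sdF <- spec@baselineSD * baseline / spec@baselineMean
    profile <- .divergenceProfile(spec)
    grp <- character(0); tp <- integer(0); st <- integer(0)
    for (i in seq_len(spec@nTimePoints) - 1L)
        for (j in seq_len(spec@samplingTimes[i + 1L]) - 1L) {
            grp <- c(grp, rep("C", spec@samplesC), rep("M", spec@samplesM))
            nij <- spec@samplesC + spec@samplesM
            tp <- c(tp, rep(i, nij))
            st <- c(st, rep(j, nij))
        }
    n <- length(grp)
    mat <- matrix(rnorm(F * n, mean = baseline, sd = sdF), F, n)
    shift <- sdF[signal] %o% (as.numeric(grp == "M") *
                              profile[tp + 1L] *
                              spec@storageDecay^st) * spec@delta
    mat[signal, ] <- mat[signal, ] + shift
    if (spec@zeroRate > 0)
        mat[matrix(runif(F * n) < spec@zeroRate, F, n)] <- 0
    if (spec@outlierRate > 0) {
        hit <- matrix(runif(F * n) < spec@outlierRate, F, n)
        mat[hit] <- mat[hit] * spec@outlierFactor
    }
    mat[mat < 0] <- 0
    dataset <- TimeCourseExperiment(
        values = t(mat), group = grp, timePoint = tp, samplingTime = st,
        featureIds = featureIds,
        sampleIds = sprintf("%s_T%d_S%d_%03d", grp, tp, st, seq_len(n)))
    list(dataset = dataset,
         truth = list(signalFeatures = featureIds[signal],
                      profile = profile,
                      storageDecay = spec@storageDecay))
}
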