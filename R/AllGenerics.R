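#' @rdname TimeCourseExperiment
#' @export
setGeneric("sampleGroup", function(x) standardGeneric("sampleGroup"))

#' @rdname TimeCourseExperiment
#' @export
setGeneric("timePoint", function(x) standardGeneric("timePoint"))

#' @rdname TimeCourseExperiment
#' @export
setGeneric("samplingTime", function(x) standardGeneric("samplingTime"))

#' @rdname TimeCourseExperiment
#' @export
setGeneric("nTimePoints", function(x) standardGeneric("nTimePoints"))

#' @rdname groupSummary
#' @export
setGeneric("groupSummary", function(x, ...) standardGeneric("groupSummary"))

#' @rdname wrdaScore
#' @export
setGeneric("wrdaScore", function(x, omega, ...) standardGeneric("wrdaScore"))

#' @rdname wrdaScore
#' @export
setGeneric("w2rdaScore", function(x, omega, ...) standardGeneric("w2rdaScore"))

#' @rdname WeightScheme-accessors
#' @export
setGeneric("weightValues", function(x) standardGeneric("weightValues"))

#' @rdname WeightScheme-accessors
#' @export
setGeneric("weightFamily", function(x) standardGeneric("weightFamily"))

#' @rdname WeightScheme-accessors
#' @export
setGeneric("changingFactor", function(x) standardGeneric("changingFactor"))

#' @rdname PermutationNull-accessors
#' @export
setGeneric("nullScores", function(x) standardGeneric("nullScores"))

#' @rdname GridResult-accessors
#' @export
setGeneric("gridTable", function(x) standardGeneric("gridTable"))
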