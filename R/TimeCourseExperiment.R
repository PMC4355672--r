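## Group label ingestion: tolerant but never silent. Anything outside the
## recognised aliases is an error, not a guess.
.normalizeGroup <- function(labels) {
    lab <- tolower(trimws(as.character(labels)))
    out <- rep(NA_character_, length(lab))
    out[lab %in% c("c", "control", "0")] <- "C"
    out[lab %in% c("m", "model", "case", "1")] <- "M"
    if (anyNA(out)) {
        bad <- which(is.na(out))
        stop(sprintf("unrecognized group label(s) %s at sample row(s) %s",
                     paste(sQuote(unique(labels[bad])), collapse = ", "),
                     paste(bad, collapse = ", ")), call. = FALSE)
    }
    out
}

## Map arbitrary time-point labels onto 0-based contiguous indices,
## keeping the original labels for reporting.
.indexLabels <- function(labels) {
    u <- sort(unique(labels))
    idx <- match(labels, u) - 1L
    list(index = idx, map = stats::setNames(seq_along(u) - 1L, as.character(u)))
}

#' Construct a TimeCourseExperiment
#'
#' Builds the package's central container from a samples-by-features
#' intensity matrix (the conventional wide orientation of an LC-MS feature
#' table) plus per-sample group, time-point and sampling-time metadata.
#' Time-point and sampling-time labels may be arbitrary ordered values;
#' they are mapped to 0-based contiguous indices (the label-to-index maps
#' are kept in \code{metadata()}).
#'
#' @param values numeric matrix, samples x features; non-negative
#'   intensities, zeros allowed, no missing values
#' @param group per-sample group labels; \code{"C"}/\code{"control"}/\code{"0"}
#'   and \code{"M"}/\code{"model"}/\code{"case"}/\code{"1"} are recognised
#'   (case-insensitively)
#' @param timePoint per-sample time-point labels (sortable; mapped to 0..N-1)
#' @param samplingTime per-sample sampling-time labels within each time
#'   point (default 0 for single-batch designs)
#' @param featureIds feature identifiers; defaults to \code{colnames(values)}
#' @param sampleIds sample identifiers; defaults to \code{rownames(values)}
#' @return a \linkS4class{TimeCourseExperiment}
#' @examples
#' x <- TimeCourseExperiment(
#'     values = matrix(rexp(24, 1 / 100), nrow = 8,
#'                     dimnames = list(paste0("s", 1:8), paste0("F", 1:3))),
#'     group = rep(c("C", "M"), 4),
#'     timePoint = rep(0:3, each = 2))
#' sampleGroup(x)
#' @export
TimeCourseExperiment <- function(values, group, timePoint,
                                 samplingTime = rep(0L, length(group)),
                                 featureIds = colnames(values),
                                 sampleIds = rownames(values)) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    n <- nrow(values)
    if (length(group) != n || length(timePoint) != n ||
        length(samplingTime) != n)
        stop("group, timePoint and samplingTime must have one entry per sample")
    if (is.null(featureIds))
        featureIds <- paste0("F", seq_len(ncol(values)))
    if (is.null(sampleIds))
        sampleIds <- paste0("S", seq_len(n))
    grp <- .normalizeGroup(group)
    tp <- .indexLabels(timePoint)
    ## sampling times indexed within each time point
    st <- integer(n)
    stMaps <- list()
    for (i in sort(unique(tp$index))) {
        sel <- tp$index == i
        m <- .indexLabels(samplingTime[sel])
        st[sel] <- m$index
        stMaps[[as.character(i)]] <- m$map
    }
    cd <- DataFrame(group = grp, timePoint = tp$index, samplingTime = st,
                    row.names = make.unique(as.character(sampleIds)))
    assays <- SimpleList(intensity = t(values))
    rownames(assays$intensity) <- as.character(featureIds)
    colnames(assays$intensity) <- rownames(cd)
    se <- SummarizedExperiment(assays = assays, colData = cd)
    metadata(se)$timePointMap <- tp$map
    metadata(se)$samplingTimeMaps <- stMaps
    new("TimeCourseExperiment", se)
}

#' @rdname TimeCourseExperiment
#' @param x a \linkS4class{TimeCourseExperiment}
#' @export
setMethod("sampleGroup", "TimeCourseExperiment",
          function(x) colData(x)$group)

#' @rdname TimeCourseExperiment
#' @export
setMethod("timePoint", "TimeCourseExperiment",
          function(x) colData(x)$timePoint)

#' @rdname TimeCourseExperiment
#' @export
setMethod("samplingTime", "TimeCourseExperiment",
          function(x) colData(x)$samplingTime)

#' @rdname TimeCourseExperiment
#' @export
setMethod("nTimePoints", "TimeCourseExperiment",
          function(x) length(unique(colData(x)$timePoint)))

setMethod("show", "TimeCourseExperiment", function(object) {
    callNextMethod()
    tp <- timePoint(object)
    cat(sprintf("time points: %d | samples C/M: %d/%d\n",
                length(unique(tp)),
                sum(sampleGroup(object) == "C"),
                sum(sampleGroup(object) == "M")))
})

#' Diagnose design problems in a time-course dataset
#'
#' Checks the design-level invariants that scoring relies on and returns
#' human-readable diagnostics instead of raising errors: at least two time
#' points, contiguous 0-based time-point indices, contiguous sampling-time
#' indices within each time point, and both groups represented at every
#' (time point, sampling time) stratum. An empty character vector means
#' the dataset is clean.
#'
#' @param x a \linkS4class{TimeCourseExperiment}
#' @return character vector of diagnostics (length 0 if none)
#' @export
validateTimeCourse <- function(x) {
    stopifnot(is(x, "TimeCourseExperiment"))
    diag <- character()
    tp <- timePoint(x)
    st <- samplingTime(x)
    grp <- sampleGroup(x)
    utp <- sort(unique(tp))
    if (length(utp) < 2L)
        diag <- c(diag, "fewer than two time points")
    if (!identical(utp, seq(0L, length(utp) - 1L)))
        diag <- c(diag, sprintf(
            "time-point indices not contiguous from 0: {%s}",
            paste(utp, collapse = ", ")))
    for (i in utp) {
        ust <- sort(unique(st[tp == i]))
        if (!identical(ust, seq(0L, length(ust) - 1L)))
            diag <- c(diag, sprintf(
                "sampling-time indices at time point %d not contiguous: {%s}",
                i, paste(ust, collapse = ", ")))
        for (j in ust) {
            sel <- tp == i & st == j
            for (g in c("C", "M"))
                if (!any(grp[sel] == g))
                    diag <- c(diag, sprintf(
                        "no samples for group %s at (time point %d, sampling time %d)",
                        g, i, j))
        }
    }
    if (any(assay(x, "intensity") < 0))
        diag <- c(diag, "negative intensities present")
    diag
}

## number of sampling times per time point, as an integer vector over 0..N-1
.samplingTimesPerPoint <- function(x) {
    tp <- timePoint(x)
    st <- samplingTime(x)
    vapply(sort(unique(tp)),
           function(i) length(unique(st[tp == i])), integer(1))
}
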