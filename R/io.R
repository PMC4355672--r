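.delimForPath <- function(path, delim) {
    if (!is.null(delim)) return(delim)
    if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a two-group time-course feature table from delimited text
#'
#' Reads a wide (one column per feature) or long (one row per
#' sample-feature pair) CSV/TSV table and returns a validated
#' \linkS4class{TimeCourseExperiment}. The delimiter is inferred from the
#' file extension (".tsv"/".txt" = tab, otherwise comma) unless given.
#'
#' @param path file to read
#' @param orientation "wide" (default) or "long"; a long table needs
#'   columns \code{feature} and \code{value} and is normalised to wide
#' @param delim field delimiter; \code{NULL} = infer from extension
#' @param sampleIdCol,groupCol,timePointCol,samplingTimeCol metadata
#'   column names; \code{samplingTimeCol} may be absent from the file
#'   (sampling time 0 assumed)
#' @param missing how to treat empty/NA feature cells: \code{"error"}
#'   (default) or \code{"zero"} (treat as non-detection)
#' @return a \linkS4class{TimeCourseExperiment}
#' @seealso [writeTimeCourse()]
#' @export
readTimeCourse <- function(path, orientation = c("wide", "long"),
                           delim = NULL,
                           sampleIdCol = "sample_id", groupCol = "group",
                           timePointCol = "time_point",
                           samplingTimeCol = "sampling_time",
                           missing = c("error", "zero")) {
    orientation <- match.arg(orientation)
    missing <- match.arg(missing)
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    delim <- .delimForPath(path, delim)
    df <- read.delim(path, sep = delim, header = TRUE,
                     check.names = FALSE, stringsAsFactors = FALSE)
    for (col in c(sampleIdCol, groupCol, timePointCol))
        if (!col %in% colnames(df))
            stop(sprintf("metadata column '%s' not found in %s", col, path))
    hasSt <- samplingTimeCol %in% colnames(df)
    if (orientation == "long") {
        for (col in c("feature", "value"))
            if (!col %in% colnames(df))
                stop(sprintf("long table needs a '%s' column", col))
        feats <- unique(df$feature)
        samp <- !duplicated(df[[sampleIdCol]])
        sids <- df[[sampleIdCol]][samp]
        values <- matrix(NA_real_, length(sids), length(feats),
                         dimnames = list(sids, feats))
        values[cbind(match(df[[sampleIdCol]], sids),
                     match(df$feature, feats))] <- as.numeric(df$value)
        meta <- df[samp, , drop = FALSE]
        df <- cbind(meta[setdiff(colnames(meta), c("feature", "value"))],
                    as.data.frame(values, check.names = FALSE))
    }
    metaCols <- c(sampleIdCol, groupCol, timePointCol,
                  if (hasSt) samplingTimeCol)
    featCols <- setdiff(colnames(df), metaCols)
    if (!length(featCols)) stop("no feature columns found")
    values <- matrix(NA_real_, nrow(df), length(featCols),
                     dimnames = list(df[[sampleIdCol]], featCols))
    for (k in seq_along(featCols)) {
        v <- df[[featCols[k]]]
        num <- suppressWarnings(as.numeric(v))
        bad <- which(is.na(num) & !is.na(v) & trimws(as.character(v)) != "")
        if (length(bad))
            stop(sprintf("non-numeric value %s in column '%s', row %d",
                         sQuote(v[bad[1]]), featCols[k], bad[1]))
        values[, k] <- num
    }
    if (anyNA(values)) {
        if (missing == "error") {
            bad <- which(is.na(values), arr.ind = TRUE)[1, ]
            stop(sprintf(
                "missing value in column '%s', row %d (use missing = \"zero\" to zero-fill)",
                featCols[bad[2]], bad[1]))
        }
        values[is.na(values)] <- 0
    }
    TimeCourseExperiment(
        values = values,
        group = df[[groupCol]],
        timePoint = df[[timePointCol]],
        samplingTime = if (hasSt) df[[samplingTimeCol]]
                       else rep(0L, nrow(df)),
        featureIds = featCols,
        sampleIds = df[[sampleIdCol]])
}

#' Write a time-course dataset as a wide delimited table
#'
#' Writes the dataset in the wide orientation that [readTimeCourse()]
#' reads back: metadata columns \code{sample_id}, \code{group},
#' \code{time_point}, \code{sampling_time}, then one column per feature.
#' Numeric values are written with 17 significant digits so a write/read
#' round trip reproduces them bit for bit.
#'
#' @param x a \linkS4class{TimeCourseExperiment}
#' @param path output file; extension picks the delimiter unless
#'   \code{delim} is given
#' @param delim field delimiter; \code{NULL} = infer from extension
#' @return \code{path}, invisibly
#' @export
writeTimeCourse <- function(x, path, delim = NULL) {
    stopifnot(is(x, "TimeCourseExperiment"))
    delim <- .delimForPath(path, delim)
    vals <- t(assay(x, "intensity"))
    num <- apply(vals, 2, function(col) sprintf("%.17g", col))
    if (is.null(dim(num))) num <- matrix(num, nrow = nrow(vals))
    colnames(num) <- colnames(vals)
    out <- cbind(data.frame(sample_id = colnames(x),
                            group = sampleGroup(x),
                            time_point = timePoint(x),
                            sampling_time = samplingTime(x),
                            check.names = FALSE),
                 as.data.frame(num, check.names = FALSE))
    write.table(out, path, sep = delim, quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}
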