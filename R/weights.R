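#' Generate a time-point or sampling-time weight vector
#'
#' Produces the weight vector of one of the four supported families over
#' \code{n} ordered indices, with index 0 the most heavily weighted (the
#' reference stage — e.g. the diagnosis stage of a prospective cohort, or
#' the batch with the shortest storage time):
#' \describe{
#'   \item{equal}{constant weights (identical to any parametric family at
#'     \code{q = 0})}
#'   \item{linear}{\eqn{1 + (n-i-1)q}}
#'   \item{proportional}{\eqn{(1+q)^{n-i-1}}}
#'   \item{exponential}{\eqn{e^{(n-i-1)q}}}
#' }
#' The changing factor \code{q >= 0} sets the steepness; all three
#' parametric families collapse to equal weights at \code{q = 0}.
#'
#' @param family "equal", "linear", "proportional" or "exponential"
#' @param q changing factor, a non-negative real; ignored for "equal"
#' @param n number of weights (time points N, or sampling times p_i)
#' @param normalize divide by the sum so weights total 1 (default TRUE)
#' @return a \linkS4class{WeightScheme}
#' @examples
#' weightValues(makeWeights("exponential", q = 0.5, n = 5, normalize = FALSE))
#' weightValues(makeWeights("equal", n = 8))   # 1/8 each
#' @export
makeWeights <- function(family = c("equal", "linear", "proportional",
                                   "exponential"),
                        q = 0, n, normalize = TRUE) {
    family <- match.arg(family)
    if (length(n) != 1L || n < 1L || n != as.integer(n))
        stop("n must be a positive integer")
    if (family != "equal") {
        if (length(q) != 1L || !is.finite(q) || q < 0)
            stop("q must be a non-negative real")
    } else q <- NA_real_
    i <- seq_len(n) - 1L
    expo <- n - i - 1L
    values <- switch(family,
        equal        = rep(1, n),
        linear       = 1 + expo * q,
        proportional = (1 + q)^expo,
        exponential  = exp(expo * q))
    if (normalize) values <- values / sum(values)
    new("WeightScheme", family = family, q = q, values = values,
        normalized = normalize)
}

#' Wrap an explicit weight vector
#'
#' For designs where the weights come from prior knowledge rather than a
#' parametric family — e.g. concentrating all weight on the time points
#' known to mark distinct disease stages and zeroing out the rest.
#'
#' @param values non-negative weights, at least one positive
#' @param normalize divide by the sum (default FALSE: explicit vectors
#'   such as (0.3, 0.3, 0.4) are usually already on the intended scale)
#' @return a \linkS4class{WeightScheme}
#' @examples
#' explicitWeights(c(0.3, 0, 0, 0.3, 0, 0, 0.4, 0))
#' @export
explicitWeights <- function(values, normalize = FALSE) {
    if (!length(values) || any(!is.finite(values)) || any(values < 0))
        stop("weights must be finite and non-negative")
    if (all(values == 0)) stop("at least one weight must be positive")
    values <- as.numeric(values)
    if (normalize) values <- values / sum(values)
    new("WeightScheme", family = "explicit", q = NA_real_,
        values = values, normalized = normalize || abs(sum(values) - 1) <= 1e-12)
}

#' @rdname WeightScheme-accessors
#' @title Accessors for WeightScheme objects
#' @param x a \linkS4class{WeightScheme}
#' @export
setMethod("weightValues", "WeightScheme", function(x) x@values)

#' @rdname WeightScheme-accessors
#' @export
setMethod("weightFamily", "WeightScheme", function(x) x@family)

#' @rdname WeightScheme-accessors
#' @export
setMethod("changingFactor", "WeightScheme", function(x) x@q)

setMethod("length", "WeightScheme", function(x) length(x@values))

setMethod("show", "WeightScheme", function(object) {
    cat(sprintf("WeightScheme: %s%s, length %d%s\n",
                object@family,
                if (is.na(object@q)) "" else sprintf(" (q = %g)", object@q),
                length(object@values),
                if (object@normalized) ", normalized" else ""))
    cat(" ", paste(signif(object@values, 4), collapse = " "), "\n")
})
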