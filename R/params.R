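#' Parameter set for the [0,1] right-truncated exponential-Rayleigh model
#'
#' Validates the two parameters and carries the derived truncation normalizer
#' \eqn{Z = 1 - e^{-(\delta + \lambda/2)}}, the parent cumulative distribution
#' evaluated at 1. `Z` is always recomputed from `(delta, lam)`; it cannot be
#' set independently.
#'
#' @param delta Scale-like parameter \eqn{\delta > 0} (exponential hazard
#'   component, per unit of x).
#' @param lam Shape-like parameter \eqn{\lambda > 0} (Rayleigh hazard
#'   component, per unit of x squared).
#' @return An object of class `rter_params` with fields `delta`, `lam`, `Z`.
#' @examples
#' p <- rter_params(1.5, 2.5)
#' p$Z  # 1 - exp(-2.75)
#' @export
rter_params <- function(delta, lam) {
  check_rter_par(delta, lam)
  structure(
    list(delta = as.numeric(delta), lam = as.numeric(lam),
         Z = rter_normalizer(delta, lam)),
    class = "rter_params"
  )
}

# truncation normalizer Z = 1 - exp(-(delta + lam/2)), via expm1 for precision
# at small parameters; 0 < Z < 1 for all finite positive (delta, lam)
rter_normalizer <- function(delta, lam) -expm1(-(delta + lam / 2))

check_rter_par <- function(delta, lam) {
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta <= 0) {
    stop("'delta' must be a single finite positive number", call. = FALSE)
  }
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam <= 0) {
    stop("'lam' must be a single finite positive number", call. = FALSE)
  }
  invisible(TRUE)
}

# Accept either an rter_params object or (delta, lam) scalars; returns the
# validated pair. Internal plumbing so user-facing functions take both styles.
as_rter_par <- function(delta, lam = NULL) {
  if (inherits(delta, "rter_params")) {
    return(c(delta$delta, delta$lam))
  }
  check_rter_par(delta, lam)
  c(delta, lam)
}

#' @export
print.rter_params <- function(x, ...) {
  cat(sprintf(
    "[0,1] right-truncated exponential-Rayleigh parameters\n  delta = %g, lambda = %g  (normalizer Z = %.6f)\n",
    x$delta, x$lam, x$Z))
  invisible(x)
}

#' Validated unit-interval sample
#'
#' Constructs a validated sample of observations on the unit interval, the
#' data container used by the likelihood and fitting functions. Observations
#' must be finite and lie in \eqn{(0, 1]}: zeros are rejected because observed
#' lifetimes are strictly positive, while values equal to 1 (the truncation
#' point) are allowed.
#'
#' @param x Numeric vector of observations.
#' @return An object of class `unit_sample`: the numeric vector with an `n`
#'   attribute.
#' @examples
#' s <- unit_sample(c(0.2, 0.5, 0.9))
#' length(s)
#' @export
unit_sample <- function(x) {
  if (inherits(x, "unit_sample")) return(x)
  if (!is.numeric(x) || length(x) < 1L) {
    stop("sample must contain at least one numeric observation", call. = FALSE)
  }
  x <- as.numeric(x)
  bad <- !is.finite(x)
  if (any(bad)) {
    stop(sprintf("non-finite observation(s) at position(s): %s",
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  out <- x <= 0 | x > 1
  if (any(out)) {
    stop(sprintf(
      "observation(s) outside (0, 1] at position(s): %s (values: %s)",
      paste(which(out), collapse = ", "),
      paste(signif(x[out], 6), collapse = ", ")), call. = FALSE)
  }
  structure(x, n = length(x), class = c("unit_sample", "numeric"))
}

#' @export
print.unit_sample <- function(x, ...) {
  cat(sprintf("unit_sample: n = %d, range [%g, %g], mean %.4f\n",
              length(x), min(x), max(x), mean(x)))
  invisible(x)
}
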