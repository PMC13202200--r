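#' The [0,1] right-truncated exponential-Rayleigh distribution
#'
#' Density, distribution function, survival function, hazard function,
#' quantile function and random generation for the exponential-Rayleigh
#' distribution right-truncated to the unit interval. The parent model has
#' cumulative hazard \eqn{H(x) = \delta x + (\lambda/2) x^2}, so that on
#' \eqn{[0,1]}
#' \deqn{g(x) = \frac{(\delta + \lambda x)\, e^{-(\delta x + \lambda x^2/2)}}{Z},
#'   \qquad G(x) = \frac{1 - e^{-(\delta x + \lambda x^2/2)}}{Z},}
#' with normalizer \eqn{Z = 1 - e^{-(\delta + \lambda/2)}}. The density at the
#' origin equals \eqn{\delta/Z}; the hazard increases without bound as
#' \eqn{x \to 1^-} because the survival function vanishes at the truncation
#' point.
#'
#' The quantile function is available in closed form as the positive root of a
#' quadratic,
#' \deqn{Q(u) = \frac{-\delta + \sqrt{\delta^2 - 2\lambda \log(1 - uZ)}}{\lambda},}
#' evaluated internally in the conjugate form
#' \eqn{2r/(\delta + \sqrt{\delta^2 + 2\lambda r})} with
#' \eqn{r = -\log(1 - uZ)}, which is numerically stable as
#' \eqn{\lambda \to 0}. Random generation uses inverse-transform sampling
#' through `Q`, so it is reproducible under [set.seed()].
#'
#' @param x,q Vector of quantiles.
#' @param p Vector of probabilities.
#' @param n Number of observations to generate.
#' @param delta Scale-like parameter \eqn{\delta > 0}, or an [rter_params]
#'   object (in which case `lam` is ignored).
#' @param lam Shape-like parameter \eqn{\lambda > 0}.
#' @param log,log.p Logical; if `TRUE`, probabilities/densities are returned
#'   on the log scale.
#' @param lower.tail Logical; if `TRUE` (default), probabilities are
#'   \eqn{P(X \le x)}, otherwise \eqn{P(X > x)}.
#' @return `drter` gives the density (0 outside \eqn{[0,1]}), `prter` the
#'   distribution function, `srter` the survival function, `hrter` the hazard
#'   (`Inf` at `x = 1`), `qrter` the quantile function, and `rrter` generates
#'   random deviates in \eqn{(0,1)}.
#' @examples
#' drter(0.5, 1.5, 2.5)        # 1.0153
#' prter(0.5, 1.5, 2.5)        # 0.6991
#' qrter(0.5, 1.5, 2.5)        # median, 0.3300
#' set.seed(1); rrter(5, 1.5, 2.5)
#' @name rter
NULL

# cumulative parent hazard H(x) = delta*x + lam*x^2/2
rter_chaz <- function(x, delta, lam) x * (delta + lam * x / 2)

#' @rdname rter
#' @export
drter <- function(x, delta, lam = NULL, log = FALSE) {
  pr <- as_rter_par(delta, lam)
  delta <- pr[1]; lam <- pr[2]
  logZ <- log(rter_normalizer(delta, lam))
  inside <- is.finite(x) & x >= 0 & x <= 1
  ld <- rep(-Inf, length(x))
  xi <- x[inside]
  ld[inside] <- log(delta + lam * xi) - rter_chaz(xi, delta, lam) - logZ
  ld[is.na(x)] <- NA_real_
  if (log) ld else exp(ld)
}

#' @rdname rter
#' @export
prter <- function(q, delta, lam = NULL, lower.tail = TRUE, log.p = FALSE) {
  pr <- as_rter_par(delta, lam)
  delta <- pr[1]; lam <- pr[2]
  Z <- rter_normalizer(delta, lam)
  x <- pmin(pmax(q, 0), 1)
  p <- -expm1(-rter_chaz(x, delta, lam)) / Z
  # clamp roundoff; q > 1 is exactly 1, q < 0 exactly 0 by the pmin/pmax above
  p <- pmin(pmax(p, 0), 1)
  p[is.na(q)] <- NA_real_
  if (!lower.tail) p <- 1 - p
  if (log.p) log(p) else p
}

#' @rdname rter
#' @export
srter <- function(q, delta, lam = NULL) {
  pr <- as_rter_par(delta, lam)
  delta <- pr[1]; lam <- pr[2]
  Z <- rter_normalizer(delta, lam)
  W <- delta + lam / 2
  x <- pmin(pmax(q, 0), 1)
  # (e^{-H(x)} - e^{-W}) / Z with the difference kept in expm1 form so the
  # cancellation near x = 1 is benign
  s <- exp(-W) * expm1(W - rter_chaz(x, delta, lam)) / Z
  s <- pmin(pmax(s, 0), 1)
  s[x == 0] <- 1                    # exact endpoints
  s[x == 1] <- 0
  s[is.na(q)] <- NA_real_
  s
}

#' @rdname rter
#' @export
hrter <- function(x, delta, lam = NULL) {
  pr <- as_rter_par(delta, lam)
  delta <- pr[1]; lam <- pr[2]
  if (any(x < 0 | x > 1, na.rm = TRUE)) {
    stop("hazard is defined on [0, 1] only (Inf at x = 1)", call. = FALSE)
  }
  W <- delta + lam / 2
  # pdf/sf with the common e^{-H(x)}/Z cancelled:
  # h(x) = (delta + lam*x) / expm1(W - H(x)) * e^{W - H(x)}
  d <- W - rter_chaz(x, delta, lam)
  h <- (delta + lam * x) * exp(d) / expm1(d)
  h[x == 1] <- Inf
  h
}

#' @rdname rter
#' @export
qrter <- function(p, delta, lam = NULL, lower.tail = TRUE, log.p = FALSE) {
  pr <- as_rter_par(delta, lam)
  delta <- pr[1]; lam <- pr[2]
  if (log.p) p <- exp(p)
  if (!lower.tail) p <- 1 - p
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  Z <- rter_normalizer(delta, lam)
  r <- -log1p(-p * Z)              # = -log(1 - p Z) >= 0
  x <- 2 * r / (delta + sqrt(delta^2 + 2 * lam * r))
  x[p == 1] <- 1                   # exact endpoint (r = delta + lam/2 there)
  x
}

#' @rdname rter
#' @export
rrter <- function(n, delta, lam = NULL) {
  if (length(n) != 1L || !is.finite(n) || n < 1) {
    stop("'n' must be a positive integer", call. = FALSE)
  }
  qrter(stats::runif(n), delta, lam)
}

#' Median of the [0,1] right-truncated exponential-Rayleigh distribution
#'
#' Closed-form median, the quantile function evaluated at \eqn{u = 1/2}.
#'
#' @inheritParams rter
#' @return The median, a number in \eqn{(0,1)}.
#' @examples
#' rter_median(1.5, 2.5)  # 0.3300
#' @export
rter_median <- function(delta, lam = NULL) qrter(0.5, delta, lam)
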