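#' Order-statistic density
#'
#' Density of the P-th order statistic of a random sample of size K from the
#' [0,1] right-truncated exponential-Rayleigh distribution,
#' \deqn{g_{P,K}(x) = \frac{K!}{(P-1)!\,(K-P)!}\;
#'   \frac{\big(1 - e^{-H(x)}\big)^{P-1}
#'         \big(e^{-H(x)} - e^{-H(1)}\big)^{K-P}
#'         (\delta + \lambda x)\, e^{-H(x)}}{Z^{K}},}
#' with \eqn{H(x) = \delta x + \lambda x^2/2}: all powers of the normalizer
#' are collected in the denominator. `p = 1` gives the sample-minimum density
#' and `p = k` the sample-maximum density.
#'
#' @param x Evaluation points in \eqn{[0,1]} (0 outside).
#' @param k Sample size K, a positive integer.
#' @param p Rank P, an integer with \eqn{1 \le P \le K}.
#' @inheritParams rter
#' @return Nonnegative density values; each \eqn{g_{P,K}} integrates to 1.
#' @examples
#' drter_order(0.5, k = 5, p = 3, delta = 1.5, lam = 2.5)
#' drter_order(0.4, k = 1, p = 1, delta = 1.5, lam = 2.5) == drter(0.4, 1.5, 2.5)
#' @export
drter_order <- function(x, k, p, delta, lam = NULL) {
  if (length(k) != 1L || k < 1 || k != round(k)) {
    stop("'k' must be a positive integer", call. = FALSE)
  }
  if (length(p) != 1L || p < 1 || p > k || p != round(p)) {
    stop("'p' must be an integer rank in [1, k]", call. = FALSE)
  }
  pr <- as_rter_par(delta, lam)
  delta <- pr[1]; lam <- pr[2]
  Z <- rter_normalizer(delta, lam)
  W <- delta + lam / 2
  coef <- exp(lgamma(k + 1) - lgamma(p) - lgamma(k - p + 1))
  inside <- is.finite(x) & x >= 0 & x <= 1
  out <- numeric(length(x))
  xi <- x[inside]
  H <- rter_chaz(xi, delta, lam)
  cdf_raw <- -expm1(-H)                         # 1 - e^{-H(x)}
  sf_raw <- exp(-W) * expm1(W - H)              # e^{-H(x)} - e^{-W}
  out[inside] <- coef * cdf_raw^(p - 1) * sf_raw^(k - p) *
    (delta + lam * xi) * exp(-H) / Z^k
  out[is.na(x)] <- NA_real_
  out
}
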