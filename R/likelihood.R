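#' Log-likelihood and analytic score
#'
#' For observations \eqn{x_1,\dots,x_n} in \eqn{(0,1]} the log-likelihood is
#' \deqn{\hat L = -n \log Z - \sum_i \big(\delta x_i + \tfrac{\lambda}{2} x_i^2\big)
#'   + \sum_i \log(\delta + \lambda x_i),}
#' with \eqn{Z = 1 - e^{-(\delta+\lambda/2)}}. The score components are
#' \deqn{\frac{\partial \hat L}{\partial \delta} =
#'   -\frac{n e^{-(\delta+\lambda/2)}}{Z} - \sum_i x_i + \sum_i \frac{1}{\delta + \lambda x_i},}
#' \deqn{\frac{\partial \hat L}{\partial \lambda} =
#'   -\frac{n e^{-(\delta+\lambda/2)}}{2Z} - \frac{1}{2}\sum_i x_i^2
#'   + \sum_i \frac{x_i}{\delta + \lambda x_i}.}
#'
#' @param x Observations (numeric vector or [unit_sample]); values must lie
#'   in \eqn{(0, 1]}.
#' @inheritParams rter_moment
#' @return `rter_loglik` returns the scalar log-likelihood; `rter_score`
#'   returns the named length-2 gradient `c(delta = ..., lam = ...)`.
#' @examples
#' x <- c(0.2, 0.5, 0.8)
#' rter_loglik(x, 1.5, 2.5)
#' rter_score(x, 1.5, 2.5)
#' @export
rter_loglik <- function(x, delta, lam = NULL) {
  x <- unit_sample(x)
  pr <- as_rter_par(delta, lam)
  delta <- pr[1]; lam <- pr[2]
  n <- length(x)
  -n * log(rter_normalizer(delta, lam)) -
    sum(rter_chaz(x, delta, lam)) +
    sum(log(delta + lam * x))
}

#' @rdname rter_loglik
#' @export
rter_score <- function(x, delta, lam = NULL) {
  x <- unit_sample(x)
  pr <- as_rter_par(delta, lam)
  delta <- pr[1]; lam <- pr[2]
  n <- length(x)
  E <- exp(-(delta + lam / 2))
  Z <- rter_normalizer(delta, lam)
  den <- delta + lam * x
  c(delta = -n * E / Z - sum(x) + sum(1 / den),
    lam   = -n * E / (2 * Z) - sum(x^2) / 2 + sum(x / den))
}

# observed information (negative Hessian) of the log-likelihood, analytic;
# used by the Newton polish in rter_fit
rter_neg_hessian <- function(x, delta, lam) {
  n <- length(x)
  W <- delta + lam / 2
  E <- exp(-W)
  Z <- 1 - E
  den <- delta + lam * x
  # d/d delta of E/Z = -E/Z - E^2/Z^2 ... note d(E)/d delta = -E, dZ = E
  g <- E / Z^2                         # common factor: E/Z^2 = d(-E/Z)/ddelta / 1
  h11 <- -n * g + sum(1 / den^2)
  h12 <- -n * g / 2 + sum(x / den^2)
  h22 <- -n * g / 4 + sum(x^2 / den^2)
  matrix(c(h11, h12, h12, h22), 2L, 2L)
}
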