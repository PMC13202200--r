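#' Renyi and Shannon entropy
#'
#' Renyi entropy of order \eqn{\eta},
#' \deqn{T(\eta) = \frac{1}{1-\eta} \log \int_0^1 g(x)^\eta\, dx,
#'   \qquad \eta > 0,\ \eta \ne 1,}
#' in nats. The reference route is adaptive quadrature of \eqn{g^\eta}. A
#' double-series route (binomial expansion of \eqn{(\delta + \lambda x)^\eta}
#' together with the Gaussian-factor expansion, each term an incomplete gamma
#' with upper limit \eqn{\eta\delta}) is available as a cross-check; the
#' binomial expansion converges only when \eqn{\lambda < \delta}, so the
#' series method is refused otherwise. The Shannon entropy
#' \eqn{-\int g \log g} is the \eqn{\eta \to 1} limit and is offered
#' separately.
#'
#' @param eta Entropy order, positive and different from 1.
#' @inheritParams rter_moment
#' @return Entropy in nats.
#' @examples
#' rter_renyi(2, 1.5, 2.5)    # -0.1818
#' rter_shannon(1.5, 2.5)
#' @export
rter_renyi <- function(eta, delta, lam = NULL,
                       method = c("quadrature", "series"), tol = 1e-12) {
  method <- match.arg(method)
  pr <- as_rter_par(delta, lam)
  if (length(eta) != 1L || !is.finite(eta) || eta <= 0 || eta == 1) {
    stop("'eta' must be positive and different from 1 (see rter_shannon for the limit)",
         call. = FALSE)
  }
  if (method == "quadrature") {
    I <- rter_integrate(function(x) drter(x, pr[1], pr[2])^eta)
  } else {
    if (pr[2] >= pr[1]) {
      stop("series form of the Renyi entropy requires lambda < delta; use method = \"quadrature\"",
           call. = FALSE)
    }
    I <- rter_renyi_integral_series(eta, pr[1], pr[2], tol)
  }
  log(I) / (1 - eta)
}

# integral of g^eta via the double series: sum over j (binomial in the linear
# factor) and p (expansion of the quadratic exponential); each inner term is
# gamma(2p+j+1, eta*delta) / (eta*delta)^(2p+j+1).
rter_renyi_integral_series <- function(eta, delta, lam, tol = 1e-12,
                                       max_j = 500L, max_p = 500L) {
  Z <- rter_normalizer(delta, lam)
  a <- eta * delta
  total <- 0
  bin <- 1                          # generalized binomial(eta, j), recursive
  for (j in 0:max_j) {
    cj <- bin * delta^(eta - j) * lam^j
    inner <- 0
    pc <- 1                         # (eta*lam/2)^p / p!
    for (p in 0:max_p) {
      term <- pc * gamma_ratio(2 * p + j + 1, a)
      inner <- inner + (if (p %% 2 == 0) term else -term)
      pc <- pc * eta * lam / (2 * (p + 1))
      if (term < tol && p > 2) break
    }
    total <- total + cj * inner
    if (abs(cj * inner) < tol && j > 2) break
    bin <- bin * (eta - j) / (j + 1)
  }
  total / Z^eta
}

#' @rdname rter_renyi
#' @export
rter_shannon <- function(delta, lam = NULL) {
  pr <- as_rter_par(delta, lam)
  -rter_integrate(function(x) {
    d <- drter(x, pr[1], pr[2])
    ifelse(d > 0, d * log(d), 0)
  })
}
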