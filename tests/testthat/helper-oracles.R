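# Independent numerical oracles used across the suite. These deliberately do
# not call the package's own integration/inversion helpers.

# composite Simpson quadrature, n panels (even)
simpson <- function(f, a, b, n = 2000L) {
  if (n %% 2 == 1) n <- n + 1L
  x <- seq(a, b, length.out = n + 1L)
  w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
  sum(w * f(x)) * (b - a) / (3 * n)
}

# bisection inverse of a monotone function on [0,1]
bisect01 <- function(f, target, tol = 1e-12) {
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# parameter grid used by the property tests
par_grid <- expand.grid(delta = c(0.1, 0.75, 1.5, 2.5, 3.75),
                        lam = c(0.25, 0.5, 1.5, 2.5, 3.25))

# the five parameter rows of the moment reference table
moment_rows <- data.frame(
  delta = c(1.5, 2.5, 2.75, 3.75, 0.75),
  lam = c(2.5, 1.5, 0.25, 1.25, 3.25),
  m1 = c(0.3718, 0.3028, 0.2945, 0.2355, 0.4415),
  m2 = c(0.2036, 0.1491, 0.1453, 0.0980, 0.2617),
  m3 = c(0.1331, 0.0917, 0.0903, 0.0538, 0.1788),
  m4 = c(0.0964, 0.0639, 0.0637, 0.0347, 0.1330),
  var = c(0.0654, 0.0574, 0.0586, 0.0426, 0.0669),
  sc = c(1.4489, 1.5924, 1.6304, 1.7535, NA),   # row 5 S.C/K.C printed transposed
  kc = c(-0.6758, -0.1264, 0.0166, 0.6079, NA)
)

fixture_path <- function() {
  system.file("extdata", "failure_times_50.txt", package = "rterd")
}
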