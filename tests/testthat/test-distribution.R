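test_that("parameter validation rejects invalid and accepts valid inputs", {
  expect_error(rter_params(-1, 2), "delta")
  expect_error(rter_params(1, 0), "lam")
  expect_error(rter_params(Inf, 1), "delta")
  p <- rter_params(1.5, 2.5)
  expect_equal(p$Z, 1 - exp(-2.75))
  expect_true(p$Z > 0 && p$Z < 1)
  # Z is derived, never independently settable: recompute check on a grid
  for (i in seq_len(nrow(par_grid))) {
    q <- rter_params(par_grid$delta[i], par_grid$lam[i])
    expect_gt(q$Z, 0); expect_lt(q$Z, 1)
  }
})

test_that("density matches closed-form values and its origin limit", {
  Zv <- 1 - exp(-2.75)
  expect_equal(drter(0, 1.5, 2.5), 1.5 / Zv, tolerance = 1e-12)
  expect_equal(drter(0.5, 1.5, 2.5), 1.0153, tolerance = 1e-4)
  # outside the support the density is zero
  expect_identical(drter(c(-0.2, 1.3), 1.5, 2.5), c(0, 0))
  expect_identical(drter(c(-0.2, 1.3), 1.5, 2.5, log = TRUE), c(-Inf, -Inf))
  # accepts a params object
  expect_equal(drter(0.5, rter_params(1.5, 2.5)), drter(0.5, 1.5, 2.5))
})

test_that("density integrates to 1 across the parameter grid", {
  for (i in seq_len(nrow(par_grid))) {
    d <- par_grid$delta[i]; l <- par_grid$lam[i]
    expect_equal(simpson(function(x) drter(x, d, l), 0, 1, 4000L), 1,
                 tolerance = 1e-8)
  }
})

test_that("cdf has correct endpoints, quadrature value, and monotonicity", {
  expect_identical(prter(0, 1.5, 2.5), 0)
  expect_identical(prter(1, 1.5, 2.5), 1)
  expect_identical(prter(-3, 0.3, 0.3), 0)
  expect_identical(prter(2, 0.3, 0.3), 1)
  # quadrature oracle for an interior point
  expect_equal(prter(0.5, 1.5, 2.5),
               simpson(function(x) drter(x, 1.5, 2.5), 0, 0.5, 4000L),
               tolerance = 1e-6)
  expect_equal(prter(0.5, 1.5, 2.5), 0.6991, tolerance = 1e-4)
  for (i in seq_len(nrow(par_grid))) {
    p <- prter(seq(0, 1, length.out = 201), par_grid$delta[i], par_grid$lam[i])
    expect_true(all(diff(p) >= 0))
  }
})

test_that("survival complements the cdf and hazard equals pdf/sf", {
  xs <- seq(0, 1, length.out = 101)
  for (i in seq_len(nrow(par_grid))) {
    d <- par_grid$delta[i]; l <- par_grid$lam[i]
    expect_equal(srter(xs, d, l), 1 - prter(xs, d, l), tolerance = 1e-12)
    xin <- xs[xs < 1]
    expect_equal(hrter(xin, d, l), drter(xin, d, l) / srter(xin, d, l),
                 tolerance = 1e-10)
    # sf <= 1 makes hazard dominate the density on the open support
    expect_true(all(hrter(xin, d, l) >= drter(xin, d, l) * (1 - 1e-12)))
  }
  expect_identical(srter(0, 1.5, 2.5), 1)
  expect_identical(srter(1, 1.5, 2.5), 0)
  expect_equal(srter(0.5, 1.5, 2.5), 0.3009, tolerance = 1e-4)
})

test_that("hazard limits: delta/Z at the origin, divergence at 1", {
  Zv <- 1 - exp(-2.75)
  expect_equal(hrter(0, 1.5, 2.5), 1.5 / Zv, tolerance = 1e-12)
  expect_equal(hrter(0.5, 1.5, 2.5), 1.0153 / 0.3009, tolerance = 1e-3)
  expect_identical(hrter(1, 1.5, 2.5), Inf)
  expect_error(hrter(1.5, 1.5, 2.5), "\\[0, 1\\]")
  # eventually increasing without bound near the truncation point
  h <- hrter(c(0.9, 0.99, 0.999, 0.9999), 1.5, 2.5)
  expect_true(all(diff(h) > 0))
  expect_gt(h[4], 1e3)
})

test_that("quantile function inverts the cdf and handles endpoints", {
  expect_identical(qrter(0, 1.5, 2.5), 0)
  expect_identical(qrter(1, 1.5, 2.5), 1)
  # bisection oracle for the median
  med <- bisect01(function(x) prter(x, 1.5, 2.5), 0.5)
  expect_equal(qrter(0.5, 1.5, 2.5), med, tolerance = 1e-6)
  expect_equal(qrter(0.5, 1.5, 2.5), 0.3300, tolerance = 1e-4)
  expect_equal(rter_median(1.5, 2.5), qrter(0.5, 1.5, 2.5))
  expect_error(qrter(1.2, 1.5, 2.5), "probabilities")
  # round-trips both ways, across the whole grid
  us <- seq(0, 1, length.out = 101)
  xs <- c(0.1, 0.25, 0.5, 0.9)
  for (i in seq_len(nrow(par_grid))) {
    d <- par_grid$delta[i]; l <- par_grid$lam[i]
    expect_equal(prter(qrter(us, d, l), d, l), us, tolerance = 1e-10)
    expect_equal(qrter(prter(xs, d, l), d, l), xs, tolerance = 1e-10)
    expect_true(all(diff(qrter(us, d, l)) >= 0))
  }
})

test_that("quantile evaluation is stable for tiny lambda", {
  # conjugate form must agree with the truncated-exponential limit
  d <- 2; l <- 1e-12
  u <- c(0.1, 0.5, 0.9)
  Zl <- 1 - exp(-(d + l / 2))
  expect_equal(qrter(u, d, l), -log1p(-u * Zl) / d, tolerance = 1e-9)
})

test_that("random generation is reproducible, in-range, and matches the cdf", {
  set.seed(42); a <- rrter(5, 1.5, 2.5)
  set.seed(42); b <- rrter(5, 1.5, 2.5)
  expect_identical(a, b)
  set.seed(99); x <- rrter(1e4, 1.5, 2.5)
  expect_true(all(x > 0 & x < 1))
  ks <- suppressWarnings(stats::ks.test(x, function(q) prter(q, 1.5, 2.5)))
  expect_gt(ks$p.value, 0.01)
  expect_error(rrter(0, 1, 1), "positive")
})

test_that("large-sample moments of generated draws match quadrature moments", {
  set.seed(7)
  x <- rrter(1e5, 1.5, 2.5)
  expect_equal(mean(x), 0.3718, tolerance = 0.003)
  for (r in 1:2) {
    mq <- rter_moment(r, 1.5, 2.5)
    se <- stats::sd(x^r) / sqrt(length(x))
    expect_lt(abs(mean(x^r) - mq), 4 * se)
  }
})
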