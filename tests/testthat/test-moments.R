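test_that("quadrature moments reproduce the reference table rows", {
  for (i in 1:4) {
    r <- moment_rows[i, ]
    m <- vapply(1:4, rter_moment, numeric(1), delta = r$delta, lam = r$lam)
    expect_lt(max(abs(m - c(r$m1, r$m2, r$m3, r$m4))), 5e-4)
  }
  # row 5: moments and variance verify; the printed shape coefficients are
  # transposed there, so only recomputed values are asserted
  r5 <- moment_rows[5, ]
  m5 <- vapply(1:4, rter_moment, numeric(1), delta = r5$delta, lam = r5$lam)
  expect_lt(max(abs(m5 - c(r5$m1, r5$m2, r5$m3, r5$m4))), 5e-4)
  expect_lt(abs(m5[3] / m5[2]^1.5 - 1.3355), 2e-3)
  expect_lt(abs(m5[4] / m5[2]^2 - 3 - (-1.0585)), 2e-3)
})

test_that("moment summary computes variance and raw-moment shape coefficients", {
  s <- rter_moments(1.5, 2.5)
  expect_equal(s$variance, s$m2 - s$m1^2)
  expect_lt(abs(s$variance - 0.0654), 5e-4)
  expect_equal(s$skew_raw, s$m3 / s$m2^1.5)
  expect_equal(s$kurt_raw, s$m4 / s$m2^2 - 3)
  expect_lt(abs(s$kurt_raw - (0.0964 / 0.2036^2 - 3)), 2e-3)
  s2 <- rter_moments(2.5, 1.5)
  expect_lt(abs(s2$skew_raw - 1.5924), 2e-3)
  expect_lt(abs(s2$variance - 0.0574), 5e-4)
  # raw-moment coefficients are not the central-moment ones
  expect_false(isTRUE(all.equal(s$skew_raw, s$skewness, tolerance = 1e-2)))
})

test_that("raw moments decrease in the order r on every grid point", {
  for (i in seq_len(nrow(par_grid))) {
    m <- vapply(1:4, rter_moment, numeric(1),
                delta = par_grid$delta[i], lam = par_grid$lam[i])
    expect_true(all(diff(m) < 0))
    expect_true(all(m > 0 & m < 1))
  }
})

test_that("series moments agree with quadrature across the grid", {
  for (i in seq_len(nrow(moment_rows))) {
    d <- moment_rows$delta[i]; l <- moment_rows$lam[i]
    for (r in 1:4) {
      expect_equal(rter_moment(r, d, l, method = "series", tol = 1e-12),
                   rter_moment(r, d, l), tolerance = 1e-8)
    }
  }
  expect_equal(rter_moment(1, 1.5, 2.5, method = "series"), 0.3718,
               tolerance = 5e-4)
})

test_that("series moments collapse to the truncated-exponential closed form as lambda -> 0", {
  d <- 2; l <- 1e-13
  for (r in 1:3) {
    closed <- (pgamma(d, r + 1) * gamma(r + 1)) / (d^r * (1 - exp(-d)))
    expect_equal(rter_moment(r, d, l, method = "series"), closed,
                 tolerance = 1e-8)
  }
})

test_that("mgf is 1 at zero, matches Simpson quadrature, and differentiates to the mean", {
  expect_equal(rter_mgf(0, 1.5, 2.5), 1, tolerance = 1e-10)
  expect_equal(rter_mgf(0, 0.3, 3), 1, tolerance = 1e-10)
  expect_equal(rter_mgf(1, 1.5, 2.5),
               simpson(function(x) exp(x) * drter(x, 1.5, 2.5), 0, 1, 4000L),
               tolerance = 1e-8)
  # central-difference derivative at 0 equals the first raw moment
  h <- 1e-5
  dmgf <- (rter_mgf(h, 1.5, 2.5) - rter_mgf(-h, 1.5, 2.5)) / (2 * h)
  expect_equal(dmgf, rter_moment(1, 1.5, 2.5), tolerance = 1e-6)
})

test_that("mgf series agrees with quadrature where valid and errors otherwise", {
  for (t in c(-1, 0.5, 1.2)) {
    expect_equal(rter_mgf(t, 1.5, 2.5, method = "series"),
                 rter_mgf(t, 1.5, 2.5), tolerance = 1e-8)
  }
  expect_error(rter_mgf(2, 1.5, 2.5, method = "series"), "t < delta")
  # quadrature path has no such restriction
  expect_gt(rter_mgf(2, 1.5, 2.5), 1)
})
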