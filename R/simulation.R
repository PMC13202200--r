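#' Monte Carlo study of maximum-likelihood estimator performance
#'
#' For each sample size in `n`, draws `reps` independent samples from the
#' [0,1] right-truncated exponential-Rayleigh distribution with the given true
#' parameters (inverse-transform sampling), fits each by [rter_fit()], and
#' aggregates the mean estimate, bias (`mean(est) - true`) and mean squared
#' error (`mean((est - true)^2)`) per parameter.
#'
#' Replicates whose fit does not converge (score above tolerance, or an
#' optimum on the box boundary) are excluded from the aggregates and counted
#' in `n_failed`; a cell with more than 10% exclusions is flagged in the
#' `flagged` column and a warning is issued, but the study still returns.
#'
#' Reproducibility: replicate `j` of cell `i` uses
#' `set.seed((seed + 1000003*i + j) mod (2^31 - 1))`, so any cell (and any
#' single replicate) can be regenerated independently of the rest of the
#' study. Identical `seed` gives bit-identical results.
#'
#' @param delta,lam True generating parameters.
#' @param n Integer vector of sample sizes (each at least 2).
#' @param reps Number of Monte Carlo replications per sample size.
#' @param seed Master seed.
#' @param fit_fun Fitting function taking a numeric sample and returning a
#'   list with elements `coef` (length 2) and `converged`; defaults to
#'   [rter_fit()]. Exposed so the harness itself can be tested with a
#'   known degenerate estimator.
#' @return A `data.frame` of class `rter_mc_study` with one row per sample
#'   size: `n`, `mean_delta`, `mean_lam`, `mse_delta`, `bias_delta`,
#'   `mse_lam`, `bias_lam`, `se_mse_delta`, `se_bias_delta`, `se_mse_lam`,
#'   `se_bias_lam` (Monte Carlo standard errors), `n_used`, `n_failed`,
#'   `flagged`; true parameters and the seed are attached as attributes.
#' @examples
#' study <- rter_mc_study(0.25, 1.5, n = c(20, 50), reps = 25, seed = 1)
#' study
#' @export
rter_mc_study <- function(delta, lam, n = c(20L, 30L, 50L, 100L, 200L),
                          reps = 300L, seed = 1L, fit_fun = NULL) {
  check_rter_par(delta, lam)
  if (any(n < 2)) stop("all sample sizes must be at least 2", call. = FALSE)
  if (reps < 1) stop("'reps' must be at least 1", call. = FALSE)
  if (is.null(fit_fun)) {
    fit_fun <- function(x) rter_fit(x, multistart = TRUE)
  }
  rows <- lapply(seq_along(n), function(i) {
    est <- matrix(NA_real_, reps, 2L)
    ok <- logical(reps)
    for (j in seq_len(reps)) {
      set.seed(mc_substream_seed(seed, i, j))
      x <- rrter(n[i], delta, lam)
      f <- tryCatch(fit_fun(x), error = function(e) NULL)
      if (!is.null(f)) {
        est[j, ] <- unname(f$coef[1:2])
        ok[j] <- isTRUE(f$converged)
      }
    }
    e <- est[ok, , drop = FALSE]
    n_failed <- sum(!ok)
    if (nrow(e) == 0) {
      stop(sprintf("no converged replicates at n = %d", n[i]), call. = FALSE)
    }
    sqe_d <- (e[, 1] - delta)^2
    sqe_l <- (e[, 2] - lam)^2
    m <- nrow(e)
    data.frame(
      n = n[i],
      mean_delta = mean(e[, 1]), mean_lam = mean(e[, 2]),
      mse_delta = mean(sqe_d), bias_delta = mean(e[, 1]) - delta,
      mse_lam = mean(sqe_l), bias_lam = mean(e[, 2]) - lam,
      se_mse_delta = stats::sd(sqe_d) / sqrt(m),
      se_bias_delta = stats::sd(e[, 1]) / sqrt(m),
      se_mse_lam = stats::sd(sqe_l) / sqrt(m),
      se_bias_lam = stats::sd(e[, 2]) / sqrt(m),
      n_used = m, n_failed = n_failed,
      flagged = n_failed > 0.10 * reps
    )
  })
  out <- do.call(rbind, rows)
  if (any(out$flagged)) {
    warning(sprintf(
      "more than 10%% non-converged replicates at n = %s (excluded from aggregates)",
      paste(out$n[out$flagged], collapse = ", ")), call. = FALSE)
  }
  attr(out, "true") <- c(delta = delta, lam = lam)
  attr(out, "seed") <- seed
  attr(out, "reps") <- reps
  class(out) <- c("rter_mc_study", "data.frame")
  out
}

# documented substream counter scheme; kept below 2^31 - 1
mc_substream_seed <- function(seed, cell, rep) {
  as.integer((as.numeric(seed) + 1000003 * cell + rep) %% 2147483647)
}

#' Monotone-trend summary of a Monte Carlo study
#'
#' Checks, per parameter, whether the MSE decreases as the sample size grows
#' (rows are sorted by `n` internally, so input order does not matter), and
#' returns a tidy verdict table. With fewer than two sample sizes the verdict
#' is `"insufficient data"`.
#'
#' @param study A `rter_mc_study` from [rter_mc_study()].
#' @param allow_inversions Number of adjacent-pair increases tolerated while
#'   still calling the trend "decreasing (with inversions)".
#' @return A list with `table` (the study sorted by `n`), `verdicts` (named
#'   character, one per parameter), and `n_sizes`.
#' @export
rter_mc_trend <- function(study, allow_inversions = 1L) {
  stopifnot(inherits(study, "rter_mc_study"))
  s <- study[order(study$n), , drop = FALSE]
  verdict <- function(v) {
    if (length(v) < 2) return("insufficient data")
    inc <- sum(diff(v) > 0)
    if (inc == 0) "strictly decreasing"
    else if (inc <= allow_inversions) "decreasing (with inversions)"
    else "not decreasing"
  }
  list(table = s,
       verdicts = c(mse_delta = verdict(s$mse_delta),
                    mse_lam = verdict(s$mse_lam)),
       n_sizes = nrow(s))
}

#' @export
print.rter_mc_study <- function(x, digits = 4, ...) {
  tr <- attr(x, "true")
  cat(sprintf(
    "Monte Carlo MLE study: true delta = %g, lambda = %g, %d replications\n",
    tr[1], tr[2], attr(x, "reps")))
  cols <- c("n", "mean_delta", "mean_lam", "mse_delta", "bias_delta",
            "mse_lam", "bias_lam", "n_failed")
  y <- as.data.frame(x)[, cols]
  y[-1] <- lapply(y[-1], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write a Monte Carlo study table to CSV or JSON
#'
#' Column layout mirrors the study summary: `n`, mean, MSE and bias for each
#' parameter, plus exclusion counts.
#'
#' @param study A `rter_mc_study`.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_mc_study <- function(study, path, format = c("csv", "json")) {
  format <- match.arg(format)
  cols <- c("n", "mean_delta", "mean_lam", "mse_delta", "bias_delta",
            "mse_lam", "bias_lam", "n_used", "n_failed")
  out <- as.data.frame(study)[, cols]
  if (format == "csv") {
    utils::write.csv(out, path, row.names = FALSE)
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE)
  }
  invisible(path)
}
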