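#' Fit competitor unit-interval lifetime models
#'
#' Maximum-likelihood fits of the comparison models used alongside the
#' [0,1] right-truncated exponential-Rayleigh (RTER) distribution. Each
#' truncated competitor is its parent distribution conditioned on the unit
#' interval by dividing the parent cdf by its value at 1:
#' \describe{
#'   \item{`rte`}{right-truncated exponential, parent \eqn{1 - e^{-\theta x}}
#'     (1 parameter);}
#'   \item{`rtr`}{right-truncated Rayleigh, parent
#'     \eqn{1 - e^{-(\theta/2) x^2}} (1 parameter);}
#'   \item{`rtw`}{right-truncated Weibull, parent
#'     \eqn{1 - e^{-(x/a)^b}} (2 parameters);}
#'   \item{`er`}{the untruncated exponential-Rayleigh distribution with cdf
#'     \eqn{1 - e^{-(\delta x + \lambda x^2 / 2)}} on \eqn{x > 0}, evaluated
#'     on the data as-is (2 parameters);}
#'   \item{`rter`}{the [0,1]-truncated exponential-Rayleigh itself, via
#'     [rter_fit()] (2 parameters).}
#' }
#'
#' @param x Observations in \eqn{(0,1]}.
#' @param model Which model to fit.
#' @return A list with `model`, `coef`, `loglik`, `k`, `n`, `converged`, `ic`.
#' @seealso [compare_unit_models()] for the full ranked table.
#' @export
fit_unit_model <- function(x, model = c("rter", "rte", "rtr", "rtw", "er")) {
  model <- match.arg(model)
  x <- unit_sample(x)
  n <- length(x)
  out <- switch(model,
    rter = {
      f <- rter_fit(x)
      list(coef = f$coef, loglik = f$loglik, k = 2L, converged = f$converged ||
             f$boundary)   # a clean boundary optimum still counts as a usable fit here
    },
    rte = {
      nll <- function(th) -(-n * log(-expm1(-th)) - th * sum(x) + n * log(th))
      o <- stats::optimize(nll, c(1e-8, 500), tol = 1e-12)
      list(coef = c(theta = o$minimum), loglik = -o$objective, k = 1L,
           converged = o$minimum < 499)
    },
    rtr = {
      nll <- function(th) {
        -(-n * log(-expm1(-th / 2)) - th * sum(x^2) / 2 + sum(log(th * x)))
      }
      o <- stats::optimize(nll, c(1e-8, 1000), tol = 1e-12)
      list(coef = c(theta = o$minimum), loglik = -o$objective, k = 1L,
           converged = o$minimum < 999)
    },
    rtw = {
      nll <- function(p) {
        a <- p[1]; b <- p[2]
        -(-n * log(-expm1(-(1 / a)^b)) +
            sum(stats::dweibull(x, shape = b, scale = a, log = TRUE)))
      }
      best <- NULL
      for (st in list(c(mean(x), 1), c(0.5, 2), c(1, 0.8))) {
        o <- tryCatch(stats::optim(st, nll, method = "L-BFGS-B",
                                   lower = c(1e-6, 1e-6), upper = c(100, 100)),
                      error = function(e) NULL)
        if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
      }
      list(coef = c(scale = best$par[1], shape = best$par[2]),
           loglik = -best$value, k = 2L, converged = best$convergence == 0)
    },
    er = {
      nll <- function(p) {
        -(-sum(rter_chaz(x, p[1], p[2])) + sum(log(p[1] + p[2] * x)))
      }
      best <- NULL
      for (st in list(c(0.5, 1), c(1, 1), c(2, 0.5))) {
        o <- tryCatch(stats::optim(st, nll, method = "L-BFGS-B",
                                   lower = c(1e-8, 1e-8), upper = c(1e3, 1e3)),
                      error = function(e) NULL)
        if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
      }
      list(coef = c(delta = best$par[1], lam = best$par[2]),
           loglik = -best$value, k = 2L, converged = best$convergence == 0)
    })
  c(list(model = model, n = n), out,
    list(ic = information_criteria(out$loglik, n, out$k)))
}

#' Compare unit-interval lifetime models by information criteria
#'
#' Fits the RTER model and its four competitors ([fit_unit_model()]) to the
#' same data and tabulates negative log-likelihood, AIC, BIC, AICc and HQIC,
#' sorted by AIC (smallest, i.e. best, first). Per-model fitting failures are
#' recorded in the table rather than aborting the comparison.
#'
#' @param x Observations in \eqn{(0,1]}.
#' @param models Character vector of models to include.
#' @return A `data.frame` of class `unit_model_comparison` with columns
#'   `model`, `neg_loglik`, `AIC`, `BIC`, `AICc`, `HQIC`, `k`, `converged`.
#' @examples
#' times <- read_unit_sample(system.file("extdata", "failure_times_50.txt",
#'                                       package = "rterd"))
#' compare_unit_models(times)
#' @export
compare_unit_models <- function(x, models = c("rter", "rte", "rtw", "rtr", "er")) {
  x <- unit_sample(x)
  rows <- lapply(models, function(m) {
    f <- tryCatch(fit_unit_model(x, m), error = function(e) NULL)
    if (is.null(f)) {
      data.frame(model = m, neg_loglik = NA_real_, AIC = NA_real_,
                 BIC = NA_real_, AICc = NA_real_, HQIC = NA_real_,
                 k = NA_integer_, converged = FALSE)
    } else {
      data.frame(model = m, neg_loglik = -f$loglik,
                 AIC = f$ic[["AIC"]], BIC = f$ic[["BIC"]],
                 AICc = f$ic[["AICc"]], HQIC = f$ic[["HQIC"]],
                 k = f$k, converged = f$converged)
    }
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$AIC), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("unit_model_comparison", "data.frame")
  tab
}

#' @export
print.unit_model_comparison <- function(x, digits = 4, ...) {
  cat("Model comparison (sorted by AIC; smaller is better)\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write a model-comparison table to CSV or JSON
#'
#' Serializes the table with fixed column order
#' `model, neg_loglik, AIC, BIC, AICc, HQIC`.
#'
#' @param tab A `unit_model_comparison` from [compare_unit_models()].
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(tab, path, format = c("csv", "json")) {
  format <- match.arg(format)
  cols <- c("model", "neg_loglik", "AIC", "BIC", "AICc", "HQIC")
  out <- as.data.frame(tab)[, cols]
  if (format == "csv") {
    utils::write.csv(out, path, row.names = FALSE)
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE)
  }
  invisible(path)
}
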