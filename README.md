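# rterd

Tools for the **exponential-Rayleigh distribution right-truncated to the
unit interval** — a two-parameter lifetime model for data confined to
[0, 1]: rates, proportions, and failure times rescaled by a maximum
observable duration.

The parent exponential-Rayleigh model has cumulative hazard
H(x) = δx + (λ/2)x², blending a constant (exponential) and a linearly
increasing (Rayleigh) failure-rate component. Conditioning on X ≤ 1 divides
the parent cdf by Z = 1 − e^(−(δ+λ/2)), so that on [0, 1]

    g(x) = (δ + λx) e^(−(δx + λx²/2)) / Z,
    G(x) = (1 − e^(−(δx + λx²/2))) / Z,

with a closed-form quantile function (positive root of a quadratic in x),
hazard δ/Z at the origin and a hazard that diverges at the truncation point.

The package provides:

* `drter` / `prter` / `qrter` / `rrter`, plus `srter` (survival), `hrter`
  (hazard) and `rter_median` — the usual d/p/q/r family;
* `rter_moments`, `rter_moment`, `rter_mgf`, `rter_renyi`, `rter_shannon`,
  `drter_order` — raw moments (adaptive quadrature and an incomplete-gamma
  series), variance and shape coefficients, MGF, Rényi/Shannon entropy,
  order-statistic densities;
* `rter_fit`, `rter_loglik`, `rter_score`, `information_criteria`,
  `fit_unit_model`, `compare_unit_models` — maximum likelihood with analytic
  score, AIC/AICc/BIC/HQIC, and comparison against truncated exponential,
  Rayleigh, Weibull and the untruncated exponential-Rayleigh;
* `rter_mc_study`, `rter_mc_trend` — a Monte Carlo harness for estimator
  bias and MSE across sample sizes;
* `read_unit_sample`, `write_unit_sample`, `failure_times_50` and a CLI
  (`rter_cli()`, shipped as `inst/exec/rterd`) with subcommands
  `fit`, `compare`, `moments`, `entropy`, `simulate`, `sample`.

## Worked example

Distribution properties at (δ = 1.5, λ = 2.5):

```r
library(rterd)
rter_moments(1.5, 2.5)
#> Moments of [0,1]-RTER(delta = 1.5, lambda = 2.5)
#>   raw moments : 0.3718  0.2036  0.1331  0.0964
#>   variance    : 0.0654
#>   raw-moment coefficients   S.C = 1.4489   C.K = -0.6758
#>   central-moment skewness 0.5259, excess kurtosis -0.6757
```

The first line gives E[X^r] for r = 1..4; `S.C`/`C.K` are shape coefficients
built from *raw* moments (a convention used for this model family), while
the last line gives the familiar central-moment skewness and excess
kurtosis.

Fitting the bundled application data (failure times of 50 components, in
thousands of hours) and ranking candidate models:

```r
x <- failure_times_50()
rter_fit(x)
#> Maximum-likelihood fit, [0,1] right-truncated exponential-Rayleigh
#>   n = 50   delta-hat = 2.8576   lambda-hat = 0.0000   [boundary]
#>   log-likelihood = 14.1571   converged = FALSE
#>   AIC = -24.314   AICc = -24.059   BIC = -20.490   HQIC = -22.858

compare_unit_models(x)
#> Model comparison (sorted by AIC; smaller is better)
#>  model neg_loglik      AIC      BIC     AICc     HQIC k converged
#>    rtw   -15.5840 -27.1680 -23.3439 -26.9127 -25.7118 2      TRUE
#>    rte   -14.1571 -26.3141 -24.4021 -26.2308 -25.5860 1      TRUE
#>   rter   -14.1571 -24.3141 -20.4901 -24.0588 -22.8579 2      TRUE
#>     er   -12.8196 -21.6393 -17.8152 -21.3839 -20.1830 2      TRUE
#>    rtr    -4.2532  -6.5063  -4.5943  -6.4230  -5.7782 1      TRUE
```

On these strongly right-skewed data the likelihood has no interior maximum:
λ-hat sits on the parameter floor (`[boundary]`, `converged = FALSE`), where
the model degenerates to a right-truncated exponential — which is why `rter`
and `rte` share a likelihood and the one-parameter `rte` wins the penalty
comparison, with the truncated Weibull best overall. The fit is reported as
found; see the methods vignette for why boundary optima are flagged.

Estimator performance across sample sizes:

```r
set.seed(1)
rter_mc_study(0.25, 1.5, n = c(50, 200), reps = 200, seed = 1)
#> Monte Carlo MLE study: true delta = 0.25, lambda = 1.5, 200 replications
#>    n mean_delta mean_lam mse_delta bias_delta mse_lam bias_lam n_failed
#>   50     0.2359   1.6798    0.0219    -0.0141  1.0306   0.1798       63
#>  200     0.2257   1.5482    0.0079    -0.0243  0.4755   0.0482        2
```

MSE shrinks with n for both parameters; `n_failed` counts replicates whose
fit ended on the boundary (excluded from the averages — common at small n,
rare at n = 200).

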