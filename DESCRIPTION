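Package: rterd
Title: The [0,1] Right-Truncated Exponential-Rayleigh Distribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Density, distribution, survival, hazard, quantile and random
    generation for the exponential-Rayleigh lifetime distribution right-truncated
    to the unit interval, a two-parameter model for rates, proportions and
    rescaled failure times with cumulative hazard delta*x + (lambda/2)*x^2.
    Provides derived properties (raw moments by adaptive quadrature and by an
    incomplete-gamma series, moment generating function, Renyi and Shannon
    entropy, order-statistic densities), maximum-likelihood estimation with
    analytic score and information criteria (AIC, AICc, BIC, HQIC),
    model comparison against other unit-interval lifetime models, a Monte Carlo
    harness for estimator bias and mean squared error across sample sizes, and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
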