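Package: n2omix
Title: Mixed-Effects and Bayesian Uncertainty Analysis of N2O Emission
    Response to Nitrogen Fertilization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying uncertainty in direct nitrous oxide (N2O)
    emission due to nitrogen fertilizer application. Implements a family of
    thirteen linear and exponential mixed-effects models relating annual
    N2O-N emission to applied N dose across published field experiments,
    fitted either by approximate maximum likelihood (exact marginal Gaussian
    likelihood for linear models, adaptive Gauss-Hermite quadrature for
    exponential models) or by Markov chain Monte Carlo with vague priors.
    Provides AIC/BIC/DIC model comparison, Gelman-Rubin convergence
    diagnostics, cluster-bootstrap confidence bands and Bayesian credibility
    bands for emission due to applied N, a multi-model best-case/worst-case
    ensemble uncertainty range, comparison with the IPCC-Tier 1
    emission-factor method, emission-factor threshold doses, and a
    hierarchical synthetic-data generator for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    coda,
    jsonlite,
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
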