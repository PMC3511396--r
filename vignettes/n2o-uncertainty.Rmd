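---
title: "Quantifying uncertainty in fertilizer-driven N2O emission with n2omix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying uncertainty in fertilizer-driven N2O emission with n2omix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(n2omix)
```

## The modelling problem

National inventories commonly estimate direct N₂O emission from nitrogen
inputs with the IPCC-Tier 1 method: emission due to N is `EF * X` with a
constant emission factor `EF = 0.01` and an uncertainty range of
0.003–0.03. Compilations of published field experiments let us ask how
defensible that constant, and especially its range, are. Such data are
hierarchical — each publication contributes measurements at several doses
and replicates, under its own soils, climate, and measurement protocol —
so `n2omix` is built around mixed-effects dose-response models.

For publication *i*, dose *j*, replicate *k*:

* linear family: `Y_ijk = (mu0 + a0_i) + (mu1 + a1_i) X_ij + e_ijk`
* exponential family: `Y_ijk = exp((mu0 + a0_i) + (mu1 + a1_i) X_ij) + e_ijk`

with `a0_i ~ N(0, sigma0^2)`, `a1_i ~ N(0, sigma1^2)`,
`e_ijk ~ N(0, tau^2)`, all independent. The thirteen structures in
`model_specs()` switch the dose term on or off and each effect between
fixed and random; the two `-B` structures are the two-random-effect models
estimated by MCMC. Random effects are taken independent; the correlated
variant adds little for these data and is not implemented. Note the
residual is *additive* in both families, so exponential-family responses
are not log-normal and the marginal likelihood has no closed form.

Units throughout: doses in kg N ha⁻¹ (valid range 0–500, the upper end of
realistic field applications), emissions in kg N₂O-N ha⁻¹ yr⁻¹, `mu1` per
kg N, and for the exponential family `mu0`/`mu1` act on the log scale.

## Maximum-likelihood estimation

For linear structures the within-publication response vector is Gaussian
with covariance `sigma0^2 J + sigma1^2 x x' + tau^2 I`, and
`loglik_linear_mixed()` evaluates the exact marginal density through the
low-rank (Woodbury) identities, vectorized across publications. Linear
structures without random effects have a closed-form MLE (OLS with the
ML variance), which `fit_ml()` uses directly.

For exponential structures `loglik_nonlinear_mixed()` integrates the
random effects out per publication by adaptive Gauss–Hermite quadrature:

* The search for each publication's conditional mode runs in
  *standardized* latent coordinates `v = u / sigma`. This is essential for
  numerical behaviour: the two effects differ by two orders of magnitude
  in scale (`sigma0 ~ 0.7` vs `sigma1 ~ 0.003`), and raw-scale Newton
  steps are wildly ill-conditioned.
* Away from the mode the joint density need not be concave, so the Newton
  step uses an eigenvalue-based ridge wherever the Hessian is not negative
  definite, a trust cap of four prior SDs per iteration, and step halving;
  the handful of publications that still stall are polished by a
  per-publication BFGS pass. Gradient tolerance at the mode is `1e-8`.
* The quadrature grid (tensor product in the two-effect case) is centred
  at the mode and scaled by the local curvature. `n_nodes = 1` is the
  Laplace approximation; the default of 9 nodes per dimension balances
  accuracy (typically within `1e-4` of a dense-grid integral on hard
  single-publication cases, far better on aggregate likelihoods) against
  cost. Tests verify convergence to brute-force integration as nodes
  increase, and that the same machinery with an identity link reproduces
  the exact linear likelihood.
* The linear predictor is clamped at ±300 purely as an overflow guard; it
  cannot bind near any mode fitted to data on this scale.

`fit_ml()` maximizes over `(mu0, mu1, log sigma0, log sigma1, log tau)`
with BFGS; the log transform enforces positivity, and a variance that
collapses below `exp(-10)` is reported as 0 with a boundary flag.
Standard errors for the mean parameters come from the inverse observed
information. AIC and BIC count `mu0` and `tau` always, plus `mu1` and
each random-effect SD where present; the BIC sample size is the number of
*observations*, not publications. Percent increases in
`model_selection_table()` are computed within each response family
relative to that family's best model, matching how the selection rule is
usually applied; ties in a family minimum are broken by input order, which
only matters in pathological equal-AIC cases.

## Bayesian estimation

`run_mcmc()` samples `NL-N-RR-B` / `L-N-RR-B` under vague priors
(`mu0, mu1 ~ N(0, 1000)`, i.e. prior SD ≈ 32; `sigma0, sigma1, tau ~
U(0, 100)`). The kernel is Metropolis-within-Gibbs:

* random-walk updates for `mu0`, `mu1` and the log-transformed SDs (with
  the exp-Jacobian so the uniform priors are respected on the natural
  scale);
* a blocked joint random-walk update of each publication's `(a0_i, a1_i)`
  pair, vectorized across publications;
* two *translation* moves that shift `mu0` (resp. `mu1`) against all
  latents — the likelihood is invariant, so these cost no data pass — and
  two *group scale* moves that rescale `(sigma, a)` jointly. Both are
  standard remedies for the strong posterior coupling between a
  hierarchical mean/SD and its latents; without them the SD chains mix an
  order of magnitude more slowly.

Proposal scales adapt toward acceptance 0.44 (scalars) / 0.3 (blocks)
during burn-in only, so the post-burn-in kernel is fixed and detailed
balance holds for every retained draw. Chains start overdispersed from
seed-derived streams; runs are bit-reproducible. Defaults (3 chains ×
20,000 iterations, half burn-in, thin 10) are a test-scale choice that
reaches Gelman–Rubin values below 1.02 on simulated study-scale data;
production analyses can simply raise `n_iter`.

`gelman_rubin()` uses the second half of each chain and clamps the
statistic below at 1: the raw estimator dips under 1 by `O(1/n)` when
chains agree, and sub-unit values carry no diagnostic meaning. `dic()`
uses the *conditional* deviance, `-2 log p(y | mu, tau, a)`, with the
effective dimension `pD = Dbar - D(posterior means of parameters and
latents)`. Conditioning on the latents is the convention of mainstream
Gibbs-sampling software; a marginal-deviance DIC would give different
`pD`, so the convention is stated here deliberately.

## Uncertainty bands, the ensemble, and the IPCC comparison

`bootstrap_band()` resamples *publications* with replacement (cluster
bootstrap), relabelling duplicates as distinct groups, and refits the
model on each resample; observation-level resampling is available behind
`resample_unit` but breaks the dependence structure the mixed models are
there to capture. Bands are pointwise 2.5/97.5 percentiles of the
refitted background-subtracted predictions over a dose grid (default
0–500 by 5). Failed or non-converged refits are dropped and counted, with
an error beyond 10%. `credibility_band()` is the posterior analogue,
pushing each retained draw of `(mu0, mu1)` through the mean response.

In both cases the band's *point* curve is the median of the same
prediction ensemble, not the full-data plug-in curve: that guarantees
`lower <= point <= upper` everywhere by construction. The plug-in curve
is always available through `mean_response()` on the fitted estimates.

`select_ensemble()` keeps every model whose AIC *and* BIC are within 10%
of its family's best and appends the two Bayesian models; on the shipped
reference statistics this yields the six random-effect dose-response
models plus the two Bayesian ones. `ensemble_range()` takes the pointwise
envelope: the spread of member point predictions (equation uncertainty)
nested inside the min-lower/max-upper envelope (equations + parameters),
read as best-case/worst-case scenarios. `compare_with_ipcc()` sets this
against `EF·X` with the 0.3–3% range. `predictive_percentiles()`
propagates the *between-experiment* spread instead (drawing the random
effects, optionally the residual), which is a much wider notion of
uncertainty than the bands for the average emission; both switches
(residual inclusion, background subtraction) are explicit because
published percentile figures rarely state them.

## The synthetic-data generator

`simulate_emissions()` draws data from exactly the stochastic structure
the models assume, storing the realized publication effects so tests can
condition on them. `default_world_design()` emulates the world-scale
shape of the reference compilation: 203 publications, three doses each
(a structural control at 0 plus sampled doses), and a positive-dose
lognormal (meanlog 5.17, sdlog 0.7) truncated at 500 by inverse-CDF
sampling, with a 5% chance of extra zero doses. Those constants were
moment-matched once so the marginal dose distribution lands near the
published summaries (median ≈ 100, mean ≈ 124, max 500, a visible point
mass at 0). Replicates default to 1 per dose; real replicate counts are
not reported in the compilations and the setting is configurable.

What the generator does *not* emulate: covariate effects (soil, climate,
fertilizer type), non-Gaussian residuals, measurement-protocol
heterogeneity beyond the random effects, and continent-level dose
differences. Negative simulated emissions are kept — the Gaussian
residual model implies them, and truncating would silently change the
likelihood being tested. Passing parameter-recovery tests on these data
therefore validates the estimation machinery, not the adequacy of the
Gaussian mixed model for any particular real dataset.

## Emission-factor arithmetic

For the exponential family the marginal EF `mu1 * exp(mu0 + mu1 X)`
exceeds the average EF `(exp(mu0 + mu1 X) - exp(mu0)) / X` at every dose
(convexity), and `ef_threshold_dose()` inverts the *marginal* EF in
closed form. With the shipped reference estimates and a 1% target this
gives ≈ 217 kg N (reported to the nearest 10 kg as 220) for `NL-N-RR`
and ≈ 242 (240) for `NL-N-FR`, matching the way such thresholds are
quoted; inverting the average EF instead would not. Reporting rounds to
the nearest 10 kg, the granularity at which these thresholds are
meaningful.

## Data handling choices

Exclusion filters (`apply_exclusion_filters()`) run in a fixed order —
natural areas, NO-only measurements, organic soils, nitrification
inhibitors, grazing, dose > 500 — and a record violating several criteria
is attributed to the first, so audits are deterministic. The dose cutoff
is strict: exactly 500 is retained. Flags are evaluated per record; if a
source encodes them per experiment, expand them to rows before reading.
The canonical CSV schema is documented in `read_emission_table()`, with a
`schema` argument for remapping, since compiled datasets rarely share
column names. Unparseable numeric fields drop the row with a logged
warning, never silently.

## Problem sizes and test design

The test suite validates against independent oracles: dense-grid
integration for the quadrature, direct Cholesky multivariate-normal
evaluation (and an `nlme` cross-fit) for the linear likelihood, hand
summation for the posterior density, and brute-force percentile
recomputation for the bands. Simulation-based checks use study-scale
data (203 publications, ~600 observations) for single-run parameter
recovery and model-family ordering, 20 seeded replicates for the
bias check on `mu1`, 50 replicates × 200 resamples for bootstrap
coverage, and 3 × 20,000 MCMC iterations for Bayesian recovery — sizes
chosen to keep the full suite in a few minutes while leaving the
qualitative conclusions stable across seeds.

## Known limitations

* Estimates from the adaptive-quadrature likelihood can differ slightly
  from other approximate-ML implementations (e.g. linearization-based
  ones) on identical data; shipped reference estimates are treated as
  generating truths, not as values the optimizer must reproduce.
* DIC is conditional-deviance DIC; do not compare it with marginal-DIC
  values from other software.
* The bootstrap assumes publications are exchangeable; it does not model
  dose-design differences between publications.
* Continental/country aggregation over national dose distributions is out
  of scope: the nonlinear mean does not commute with averaging over
  doses, so country-level emission needs the national dose distribution,
  which the package does not ship.
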