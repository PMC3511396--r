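test_that("the linear marginal likelihood reduces to iid normals without random effects", {
  d <- oracle_data()
  p <- param_set(0.5, 0.01, tau = 1.3)
  expect_equal(
    loglik_linear_mixed("L-N-FF", p, d),
    sum(dnorm(d$n2o_kg_n_ha_yr, 0.5 + 0.01 * d$n_rate_kg_ha, 1.3, log = TRUE))
  )
  # one standard-normal observation
  ds <- oracle_data(x = 0, y = 0)
  expect_equal(loglik_linear_mixed("L-0-F", param_set(0, tau = 1), ds),
               -0.5 * log(2 * pi))
})

test_that("the linear marginal likelihood matches direct Cholesky MVN evaluation", {
  p <- param_set(1.0, 0.012, sigma0 = 0.7, sigma1 = 0.002, tau = 1.5)
  d <- simulate_emissions("L-N-RR", p, design_config(9), seed = 5)
  expect_equal(loglik_linear_mixed("L-N-RR", p, d), chol_mvn_loglik("L-N-RR", p, d))
  p1 <- param_set(2.0, sigma0 = 1.1, tau = 0.8)
  d1 <- simulate_emissions("L-0-R", p1, design_config(7), seed = 6)
  expect_equal(loglik_linear_mixed("L-0-R", p1, d1), chol_mvn_loglik("L-0-R", p1, d1))
})

test_that("the linear random-intercept likelihood matches 1-D numerical integration", {
  d <- oracle_data(x = c(0, 150), y = c(1.4, 3.1))
  p <- param_set(1.2, 0.011, sigma0 = 0.9, tau = 1.1)
  oracle <- trapezoid_loglik_1d(d, 1.2, 0.011, 0.9, 1.1,
                                component = "intercept", link = "identity")
  expect_equal(loglik_linear_mixed("L-N-RF", p, d), oracle, tolerance = 1e-6)
})

test_that("a zero residual SD is reported as a singular covariance", {
  d <- oracle_data()
  expect_error(loglik_linear_mixed("L-N-FF", param_set(1, 0.01, tau = 0), d),
               "singular")
})

test_that("the quadrature likelihood is exact when no variance component is present", {
  d <- oracle_data()
  p <- param_set(0.2, 0.004, tau = 1.2)
  exact <- sum(dnorm(d$n2o_kg_n_ha_yr, exp(0.2 + 0.004 * d$n_rate_kg_ha),
                     1.2, log = TRUE))
  for (k in c(1, 3, 9)) {
    expect_equal(loglik_nonlinear_mixed("NL-N-FF", p, d, n_nodes = k), exact)
  }
})

test_that("adaptive quadrature converges to dense-grid integration", {
  d <- oracle_data()
  p <- param_set(0.2, 0.004, sigma0 = 0.7, tau = 1.2)
  oracle <- trapezoid_loglik_1d(d, 0.2, 0.004, 0.7, 1.2,
                                component = "intercept", link = "log")
  errs <- sapply(c(3, 9, 15, 25), function(k) {
    abs(loglik_nonlinear_mixed("NL-N-RF", p, d, n_nodes = k) - oracle)
  })
  expect_true(all(diff(errs) < 0))             # monotone approach
  expect_lt(errs[4] / abs(oracle), 1e-5)       # dense-grid agreement

  # random-slope component
  ps <- param_set(0.3, 0.0033, sigma1 = 0.004, tau = 1.0)
  oracle_s <- trapezoid_loglik_1d(d, 0.3, 0.0033, 0.004, 1.0,
                                  component = "slope", link = "log")
  expect_lt(abs(loglik_nonlinear_mixed("NL-N-FR", ps, d, n_nodes = 25) -
                  oracle_s) / abs(oracle_s), 1e-5)
})

test_that("the quadrature machinery reproduces the linear closed form with identity link", {
  p <- param_set(1.0, 0.012, sigma0 = 0.7, sigma1 = 0.002, tau = 1.5)
  d <- simulate_emissions("L-N-RR", p, design_config(8), seed = 5)
  expect_equal(
    loglik_nonlinear_mixed("L-N-RR", p, d, n_nodes = 7, link = "identity"),
    loglik_linear_mixed("L-N-RR", p, d),
    tolerance = 1e-6
  )
  expect_error(loglik_nonlinear_mixed("L-N-RR", p, d), "identity")
  expect_error(loglik_nonlinear_mixed("NL-N-RR", ref_params("NL-N-RR"), d,
                                      n_nodes = 4), "odd")
})

test_that("likelihoods are invariant to publication relabeling and row order", {
  p <- ref_params("NL-N-RR")
  d <- simulate_emissions("NL-N-RR", p, design_config(10), seed = 9)
  ll0 <- loglik_nonlinear_mixed("NL-N-RR", p, d)
  perm <- d[sample(nrow(d)), ]
  perm$publication_id <- paste0("relabel_", perm$publication_id)
  expect_equal(loglik_nonlinear_mixed("NL-N-RR", p, perm), ll0)

  pl <- ref_params("L-N-RR")
  dl <- simulate_emissions("L-N-RR", pl, design_config(10), seed = 9)
  ll0 <- loglik_linear_mixed("L-N-RR", pl, dl)
  perm <- dl[rev(seq_len(nrow(dl))), ]
  expect_equal(loglik_linear_mixed("L-N-RR", pl, perm), ll0)
})

test_that("AIC/BIC identities and parameter counts hold", {
  d <- simulate_emissions("L-N-FF", param_set(1, 0.01, tau = 1),
                          design_config(20), seed = 4)
  f <- fit_ml("L-N-FF", d)
  expect_equal(f$n_params, 3L)
  expect_equal(f$aic, -2 * f$loglik + 2 * 3, tolerance = 1e-8)
  expect_equal(f$bic, -2 * f$loglik + 3 * log(nrow(d)), tolerance = 1e-8)

  dn <- simulate_emissions("NL-N-RR", ref_params("NL-N-RR"),
                           design_config(15), seed = 4)
  fn <- fit_ml("NL-N-RR", dn, n_nodes = 5)
  expect_equal(fn$n_params, 5L)
  expect_equal(fn$aic, -2 * fn$loglik + 10, tolerance = 1e-8)
})

test_that("the closed-form fixed-effects MLE agrees with the optimizer route", {
  d <- simulate_emissions("L-N-FF", param_set(0.8, 0.012, tau = 2),
                          design_config(40), seed = 13)
  f1 <- fit_ml("L-N-FF", d)
  f2 <- fit_ml("L-N-FF", d, control = list(force_optim = TRUE))
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f1$estimates$mu1, f2$estimates$mu1, tolerance = 1e-4)
  expect_true(f1$converged && f2$converged)
})

test_that("the maximized likelihood is no worse than the generating truth", {
  p <- ref_params("NL-N-RF")
  d <- simulate_emissions("NL-N-RF", p, design_config(25), seed = 21)
  f <- fit_ml("NL-N-RF", d, n_nodes = 5)
  expect_true(f$converged)
  expect_gte(f$loglik + 1e-6, loglik_nonlinear_mixed("NL-N-RF", p, d, n_nodes = 5))
})

test_that("intercept-only fitting recovers the mean and residual SD", {
  p <- ref_params("L-0-F")  # mu0 2.4, tau 4.26
  d <- simulate_emissions("L-0-F", p, default_world_design(), seed = 31)
  f <- fit_ml("L-0-F", d)
  expect_true(f$converged)
  expect_lt(abs(f$estimates$mu0 - p$mu0), 3 * f$se[["mu0"]])
  expect_lt(abs(f$estimates$tau / p$tau - 1), 0.1)
})

test_that("the linear mixed fit agrees with an independent mixed-model fitter", {
  skip_if_not_installed("nlme")
  p <- ref_params("L-N-RF")
  d <- simulate_emissions("L-N-RF", p, design_config(60), seed = 17)
  f <- fit_ml("L-N-RF", d)
  ref <- nlme::lme(n2o_kg_n_ha_yr ~ n_rate_kg_ha, random = ~ 1 | publication_id,
                   data = d, method = "ML")
  expect_equal(f$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-4)
  expect_equal(f$estimates$mu1, unname(nlme::fixef(ref)[2]), tolerance = 1e-3)
})

test_that("repeated simulation recovers the N-effect of the exponential mixed model", {
  # mean of mu1-hat over seeded replicates at the reference truth
  p <- ref_params("NL-N-RR")
  mu1_hat <- sapply(1:20, function(s) {
    d <- simulate_emissions("NL-N-RR", p, default_world_design(), seed = 100 + s)
    f <- fit_ml("NL-N-RR", d, n_nodes = 5)
    if (f$converged) f$estimates$mu1 else NA_real_
  })
  expect_gte(sum(!is.na(mu1_hat)), 18)
  expect_lt(abs(mean(mu1_hat, na.rm = TRUE) / p$mu1 - 1), 0.10)
})

test_that("the model-comparison table computes within-family percentages", {
  fits <- list(pseudo_fit("NL-N-RF", 100, 102), pseudo_fit("NL-N-RR", 110, 110),
               pseudo_fit("L-N-RR", 50, 55))
  tab <- model_selection_table(fits)
  expect_equal(tab$pct_aic, c(0, 10, 0))
  expect_equal(tab$pct_bic[2], 100 * (110 / 102 - 1))
  expect_equal(tab$pct_aic[tab$name == "L-N-RR"], 0)
  expect_error(
    model_selection_table(list(pseudo_fit("L-N-RR", 1, 1),
                               pseudo_fit("L-N-RR", 2, 2))),
    "duplicate"
  )
})

test_that("published model-comparison statistics reproduce their printed percentages", {
  stats <- ref_fit_stats() |> dplyr::filter(!is.na(aic))
  fits <- purrr::pmap(stats[, c("name", "aic", "bic")],
                      function(name, aic, bic) pseudo_fit(name, aic, bic))
  tab <- model_selection_table(fits)
  published_pct_aic <- c(23.0, 13.6, 1.6, 2.6, 0, 20.5, 17.4, 12.3, 9.0, 0.1, 0)
  expect_equal(tab$pct_aic, published_pct_aic, tolerance = 0.05)
})
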