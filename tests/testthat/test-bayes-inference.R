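test_that("the prior has the documented spread", {
  pr <- prior_spec()
  expect_equal(sqrt(pr$mu_var), 31.62, tolerance = 1e-3)
  expect_equal(round(sqrt(pr$mu_var)), 32)
})

test_that("the log posterior handles support and sums its three blocks", {
  d <- oracle_data(x = c(0, 100, 200), y = c(1.0, 2.0, 3.5))
  lat <- list(a0 = 0.3, a1 = -0.001)
  p <- param_set(1.1, 0.01, sigma0 = 0.8, sigma1 = 0.005, tau = 1.4)

  # outside the uniform support
  p_bad <- param_set(1.1, 0.01, sigma0 = 0.8, sigma1 = 0.005, tau = 120)
  expect_identical(log_posterior("L-N-RR-B", p_bad, lat, d), -Inf)

  # hand-summed value on three records
  musd <- sqrt(1000)
  m <- (1.1 + 0.3) + (0.01 - 0.001) * d$n_rate_kg_ha
  by_hand <- sum(dnorm(d$n2o_kg_n_ha_yr, m, 1.4, log = TRUE)) +
    dnorm(0.3, 0, 0.8, log = TRUE) + dnorm(-0.001, 0, 0.005, log = TRUE) +
    dnorm(1.1, 0, musd, log = TRUE) + dnorm(0.01, 0, musd, log = TRUE) +
    3 * log(1 / 100)
  expect_equal(log_posterior("L-N-RR-B", p, lat, d), by_hand)
})

test_that("shifting all responses and the intercept leaves the data term unchanged", {
  d <- oracle_data(x = c(0, 50, 100), y = c(1.0, 1.5, 2.0))
  lat <- list(a0 = 0.2, a1 = 0)
  p1 <- param_set(1.0, 0.01, sigma0 = 0.5, sigma1 = 0.003, tau = 1.2)
  cc <- 5
  d2 <- d
  d2$n2o_kg_n_ha_yr <- d$n2o_kg_n_ha_yr + cc
  p2 <- param_set(1.0 + cc, 0.01, sigma0 = 0.5, sigma1 = 0.003, tau = 1.2)
  musd <- sqrt(1000)
  prior_shift <- dnorm(1.0 + cc, 0, musd, log = TRUE) -
    dnorm(1.0, 0, musd, log = TRUE)
  expect_equal(log_posterior("L-N-RR-B", p2, lat, d2),
               log_posterior("L-N-RR-B", p1, lat, d) + prior_shift)
})

test_that("the Gelman-Rubin statistic separates converged from divergent chains", {
  set.seed(8)
  same <- matrix(rnorm(2e4), ncol = 2)
  expect_lt(gelman_rubin(same), 1.05)

  copies <- cbind(same[, 1], same[, 1])
  expect_equal(gelman_rubin(copies), 1.0, tolerance = 1e-6)

  apart <- cbind(rnorm(500), rnorm(500, mean = 10))
  expect_gt(gelman_rubin(apart), 1.1)

  expect_error(gelman_rubin(matrix(rnorm(100), ncol = 1)), "2 chains")
  expect_error(gelman_rubin(matrix(rnorm(8), ncol = 2)), "short")
  expect_gte(gelman_rubin(same), 1)
})

test_that("the sampler is bit-reproducible from its seed", {
  d <- simulate_emissions("L-N-RR", ref_params("L-N-RR"), design_config(8),
                          seed = 2)
  p1 <- suppressWarnings(run_mcmc("L-N-RR-B", d, n_chains = 2, n_iter = 400,
                                  thin = 2, seed = 42))
  p2 <- suppressWarnings(run_mcmc("L-N-RR-B", d, n_chains = 2, n_iter = 400,
                                  thin = 2, seed = 42))
  expect_identical(posterior_draws(p1), posterior_draws(p2))
  p3 <- suppressWarnings(run_mcmc("L-N-RR-B", d, n_chains = 2, n_iter = 400,
                                  thin = 2, seed = 43))
  expect_false(identical(posterior_draws(p1), posterior_draws(p3)))
  expect_error(run_mcmc("L-N-RR", d), "Bayesian")
})

test_that("SD draws stay inside the prior support", {
  d <- simulate_emissions("L-N-RR", ref_params("L-N-RR"), design_config(10),
                          seed = 3)
  post <- suppressWarnings(run_mcmc("L-N-RR-B", d, n_chains = 2,
                                    n_iter = 1000, seed = 5))
  dr <- posterior_draws(post)
  expect_true(all(dr[, c("sigma0", "sigma1", "tau")] > 0))
  expect_true(all(dr[, c("sigma0", "sigma1", "tau")] < 100))
})

test_that("a short run recovers the generating linear-model parameters", {
  p <- ref_params("L-N-RR")
  d <- simulate_emissions("L-N-RR", p, design_config(40), seed = 6)
  post <- suppressWarnings(run_mcmc("L-N-RR-B", d, n_iter = 6000, seed = 7))
  td <- tidy(post)
  for (term in c("mu0", "mu1")) {
    row <- td[td$term == term, ]
    expect_lt(abs(row$estimate - p[[term]]), 3 * row$std.error)
  }
})

test_that("with no data the posterior reproduces the prior spread", {
  d0 <- toy_record()[0, ]
  post <- suppressWarnings(run_mcmc("L-N-RR-B", d0, n_iter = 20000, seed = 12))
  dr <- posterior_draws(post)
  expect_lt(abs(sd(dr[, "mu1"]) - sqrt(1000)), 1)
  expect_lt(abs(mean(dr[, "mu0"])), 3)
  expect_true(max(post$psrf) < 1.1)
})

test_that("a degenerate posterior gives DIC = D(theta) with zero complexity", {
  d <- oracle_data(x = c(0, 100), y = c(1.2, 2.2))
  p <- param_set(0.9, 0.009, sigma0 = 0.6, sigma1 = 0.004, tau = 1.1)
  post <- degenerate_posterior("L-N-RR-B", p, a0 = 0.25, a1 = -0.002)
  m <- (0.9 + 0.25) + (0.009 - 0.002) * d$n_rate_kg_ha
  d_theta <- -2 * sum(dnorm(d$n2o_kg_n_ha_yr, m, 1.1, log = TRUE))
  expect_equal(dic(post, d), d_theta)
})

test_that("pD is nonnegative on a converged run", {
  p <- ref_params("L-N-RR")
  d <- simulate_emissions("L-N-RR", p, design_config(25), seed = 8)
  post <- suppressWarnings(run_mcmc("L-N-RR-B", d, n_iter = 4000, seed = 9))
  pars <- posterior_draws(post)
  a0 <- posterior_draws(post, "a0")
  a1 <- posterior_draws(post, "a1")
  dev <- sapply(seq_len(nrow(pars)), function(i) {
    lat <- list(a0 = a0[i, ], a1 = a1[i, ])
    m <- pars[i, "mu0"] + a0[i, ][match(d$publication_id, unique(d$publication_id))] +
      (pars[i, "mu1"] + a1[i, ][match(d$publication_id, unique(d$publication_id))]) *
      d$n_rate_kg_ha
    -2 * sum(dnorm(d$n2o_kg_n_ha_yr, m, pars[i, "tau"], log = TRUE))
  })
  pd <- dic(post, d) - mean(dev)
  expect_gte(pd, 0)
})

test_that("credibility bands collapse correctly and match brute-force percentiles", {
  p <- param_set(0.2, 0.004, sigma0 = 0.6, sigma1 = 0.002, tau = 1.2)
  post_deg <- degenerate_posterior("NL-N-RR-B", p, a0 = 0, a1 = 0)
  band <- credibility_band(post_deg, dose_grid = c(0, 100, 200))
  expect_equal(band$lower, band$upper)
  expect_equal(band$point, exp(0.2 + 0.004 * c(0, 100, 200)) - exp(0.2))
  expect_equal(band$point[1], 0)  # background-subtracted at dose 0

  d <- simulate_emissions("L-N-RR", ref_params("L-N-RR"), design_config(12),
                          seed = 4)
  post <- suppressWarnings(run_mcmc("L-N-RR-B", d, n_chains = 2,
                                    n_iter = 2000, seed = 5))
  grid <- c(0, 50, 250)
  band <- credibility_band(post, dose_grid = grid)
  dr <- posterior_draws(post)
  pred <- outer(dr[, "mu1"], grid)  # linear model: mu1 * x after subtraction
  expect_equal(band$lower, unname(apply(pred, 2, quantile, 0.025)))
  expect_equal(band$upper, unname(apply(pred, 2, quantile, 0.975)))
  expect_equal(band$point, unname(apply(pred, 2, median)))
  expect_error(credibility_band(post, dose_grid = numeric(0)), "empty")
})
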