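test_that("bootstrap over a single publication is degenerate", {
  d <- oracle_data(x = c(0, 50, 100, 200, 300),
                   y = c(0.8, 1.4, 1.9, 3.1, 4.4))
  d$replicate <- 1L
  band <- bootstrap_band("L-N-FF", d, B = 2, dose_grid = c(0, 100, 300),
                         seed = 1)
  expect_equal(band$lower, band$upper)
  expect_equal(band$lower[1], 0)
})

test_that("band width shrinks as the residual noise vanishes", {
  des <- design_config(30)
  width_at_100 <- function(tau) {
    d <- simulate_emissions("L-N-FF", param_set(0.7, 0.014, tau = tau),
                            des, seed = 5)
    b <- bootstrap_band("L-N-FF", d, B = 60, dose_grid = c(100), seed = 2)
    b$upper - b$lower
  }
  w_hi <- width_at_100(2.0)
  w_lo <- width_at_100(0.05)
  expect_lt(w_lo, w_hi / 10)
})

test_that("bands are reproducible from the seed and respect their invariants", {
  d <- simulate_emissions("L-N-FF", ref_params("L-N-FF"), design_config(40),
                          seed = 3)
  grid <- seq(0, 500, by = 100)
  b1 <- bootstrap_band("L-N-FF", d, B = 40, dose_grid = grid, seed = 10)
  b2 <- bootstrap_band("L-N-FF", d, B = 40, dose_grid = grid, seed = 10)
  expect_identical(as.data.frame(b1), as.data.frame(b2))
  expect_true(all(b1$lower <= b1$point & b1$point <= b1$upper))
  expect_true(all(b1[b1$dose == 0, c("lower", "point", "upper")] == 0))
})

test_that("ensemble selection applies the 10% rule within families", {
  fits <- list(pseudo_fit("NL-N-RF", 100, 100), pseudo_fit("NL-N-RR", 109, 109),
               pseudo_fit("NL-N-FR", 111, 111),
               pseudo_fit("L-N-RR", 200, 200), pseudo_fit("L-N-FR", 205, 205))
  sel <- select_ensemble(fits)
  expect_setequal(sel, c("NL-N-RF", "NL-N-RR", "L-N-RR", "L-N-FR",
                         "NL-N-RR-B", "L-N-RR-B"))

  all_equal <- list(pseudo_fit("NL-N-RF", 100, 100),
                    pseudo_fit("NL-N-RR", 100, 100),
                    pseudo_fit("L-N-RR", 100, 100))
  expect_length(select_ensemble(all_equal), 5)
})

test_that("the published fit statistics select the six random-effect dose models", {
  stats <- ref_fit_stats() |> dplyr::filter(!is.na(aic))
  fits <- purrr::pmap(stats[, c("name", "aic", "bic")],
                      function(name, aic, bic) pseudo_fit(name, aic, bic))
  sel <- select_ensemble(fits)
  expect_setequal(sel, c("NL-N-RF", "NL-N-FR", "NL-N-RR",
                         "L-N-RF", "L-N-FR", "L-N-RR",
                         "NL-N-RR-B", "L-N-RR-B"))
  expect_length(sel, 8)
})

test_that("the ensemble range is the pointwise envelope of its members", {
  grid <- c(0, 100, 200)
  mk <- function(model, point, lower, upper) {
    n2omix:::new_band(model, grid, point, lower, upper, TRUE, list())
  }
  b1 <- mk("A", c(0, 1, 2), c(0, 0.5, 1.5), c(0, 1.5, 2.5))
  b2 <- mk("B", c(0, 2, 4), c(0, 1.8, 3.5), c(0, 2.2, 4.5))
  ens <- ensemble_range(list(b1, b2))
  expect_equal(ens$lower, pmin(b1$lower, b2$lower))
  expect_equal(ens$upper, pmax(b1$upper, b2$upper))
  expect_equal(ens$eq_low, pmin(b1$point, b2$point))
  expect_equal(ens$eq_high, pmax(b1$point, b2$point))
  # equation range nested inside the full range
  expect_true(all(ens$eq_low >= ens$lower & ens$eq_high <= ens$upper))

  solo <- ensemble_range(list(b1))
  expect_equal(solo$lower, b1$lower)
  expect_equal(solo$upper, b1$upper)

  # adding a member can only widen or preserve the envelope
  b3 <- mk("C", c(0, 1.5, 3), c(0, 0.2, 1), c(0, 3, 5))
  wider <- ensemble_range(list(b1, b2, b3))
  expect_true(all(wider$lower <= ens$lower & wider$upper >= ens$upper))

  bad <- n2omix:::new_band("D", c(0, 50), c(0, 1), c(0, 0.5), c(0, 1.5),
                           TRUE, list())
  expect_error(ensemble_range(list(b1, bad)), "common dose grid")
})

test_that("random envelopes match a brute-force recompute", {
  set.seed(77)
  grid <- seq(0, 500, by = 50)
  bands <- lapply(1:8, function(i) {
    pt <- sort(runif(length(grid), 0, 5))
    lo <- pt - runif(length(grid), 0, 1)
    hi <- pt + runif(length(grid), 0, 1)
    n2omix:::new_band(paste0("m", i), grid, pt, lo, hi, TRUE, list())
  })
  ens <- ensemble_range(bands)
  lows <- sapply(bands, function(b) b$lower)
  his <- sapply(bands, function(b) b$upper)
  expect_equal(ens$lower, apply(lows, 1, min))
  expect_equal(ens$upper, apply(his, 1, max))
})

test_that("the IPCC comparison reports the published Tier 1 numbers", {
  grid <- c(0, 100, 300)
  bands <- list(n2omix:::new_band("m", grid, c(0, 1.1, 3.2), c(0, 0.8, 2.4),
                                  c(0, 1.5, 4.2), TRUE, list()))
  rep <- compare_with_ipcc(ensemble_range(bands))
  expect_equal(rep$ipcc_point, c(0, 1, 3))
  expect_equal(rep$ipcc_high, c(0, 3, 9))
  expect_equal(rep$ipcc_low, c(0, 0.3, 0.9))
  expect_true(rep$ipcc_in_equation_range[1])   # dose 0: trivially contained
  expect_true(rep$ensemble_within_ipcc[1])
  expect_true(rep$ensemble_within_ipcc[2])
})

test_that("predictive percentiles collapse, order, and match the lognormal median", {
  p0 <- param_set(0.19, 0.0037, sigma0 = 0, sigma1 = 0, tau = 1)
  q <- predictive_percentiles("NL-N-RR", p0, 100, percentiles = c(10, 50, 90),
                              n_draws = 100, seed = 1)
  expect_true(all(q$value == mean_response("NL-N-RR", p0, 100)))

  p <- param_set(0.5, sigma0 = 0.8, tau = 1)
  med <- predictive_percentiles("NL-0-R", p, 0, percentiles = 50,
                                n_draws = 2e5, seed = 2)$value
  expect_equal(med, exp(0.5), tolerance = 0.01)

  pr <- ref_params("NL-N-RR")
  q2 <- predictive_percentiles("NL-N-RR", pr, 100,
                               percentiles = c(50, 90, 95, 99),
                               n_draws = 5e4, include_residual = TRUE,
                               seed = 3)
  expect_true(all(diff(q2$value) >= 0))
  expect_error(predictive_percentiles("NL-N-RR", pr, 100, percentiles = 101),
               "between 0 and 100")
  expect_error(predictive_percentiles("NL-N-FF", ref_params("NL-N-FF"), 100),
               "random component")
})

test_that("plot methods return ggplot objects", {
  grid <- c(0, 100, 200)
  band <- n2omix:::new_band("m", grid, c(0, 1, 2), c(0, 0.5, 1.5),
                            c(0, 1.5, 2.5), TRUE, list())
  expect_s3_class(ggplot2::autoplot(band), "ggplot")
  expect_s3_class(ggplot2::autoplot(ensemble_range(list(band))), "ggplot")
  f <- fit_ml("L-N-FF", simulate_emissions("L-N-FF", ref_params("L-N-FF"),
                                           design_config(10), seed = 1))
  expect_s3_class(plot_response_curves(list(f)), "ggplot")
})
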