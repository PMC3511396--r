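# shared fixture builders; everything is generated in code

# a fully clean record with overridable fields
toy_record <- function(publication_id = "p1", n_rate_kg_ha = 100,
                       n2o_kg_n_ha_yr = 1.5, replicate = 1L,
                       land_use = "agricultural", soil_class = "mineral",
                       gas_measured = "N2O", inhibitor = FALSE,
                       grazing = FALSE) {
  tibble::tibble(
    publication_id = publication_id, n_rate_kg_ha = n_rate_kg_ha,
    n2o_kg_n_ha_yr = n2o_kg_n_ha_yr, replicate = replicate,
    land_use = land_use, soil_class = soil_class,
    gas_measured = gas_measured, inhibitor = inhibitor, grazing = grazing
  )
}

# tiny single-publication dataset for likelihood oracles
oracle_data <- function(x = c(0, 100, 200), y = c(1.1, 2.3, 4.0),
                        id = "p1") {
  tibble::tibble(publication_id = id, n_rate_kg_ha = x, n2o_kg_n_ha_yr = y)
}

# brute-force 1-D trapezoid integration of the marginal likelihood over a
# single publication's random effect (intercept or slope), exp or identity
# mean -- the independent oracle for the quadrature code
trapezoid_loglik_1d <- function(data, mu0, mu1, sigma, tau,
                                component = c("intercept", "slope"),
                                link = c("log", "identity"),
                                half_width = 8, n_grid = 1e5) {
  component <- match.arg(component)
  link <- match.arg(link)
  grid <- seq(-half_width * sigma, half_width * sigma, length.out = n_grid)
  x <- data$n_rate_kg_ha
  y <- data$n2o_kg_n_ha_yr
  eta <- outer(grid, x, function(a, xx) {
    if (component == "intercept") mu0 + a + mu1 * xx else mu0 + (mu1 + a) * xx
  })
  m <- if (link == "log") exp(eta) else eta
  ll_y <- rowSums(dnorm(matrix(y, nrow(m), ncol(m), byrow = TRUE), m, tau,
                        log = TRUE))
  f <- exp(ll_y + dnorm(grid, 0, sigma, log = TRUE))
  log(sum((f[-1] + f[-length(f)]) / 2 * diff(grid)))
}

# direct per-publication multivariate-normal evaluation via Cholesky --
# the independent oracle for the closed-form linear marginal likelihood
chol_mvn_loglik <- function(spec, p, data) {
  spec <- model_spec(spec)
  ll <- 0
  for (id in unique(data$publication_id)) {
    s <- data[data$publication_id == id, ]
    mu <- p$mu0 + if (spec$uses_N) p$mu1 * s$n_rate_kg_ha else 0
    V <- diag(p$tau^2, nrow(s))
    if (spec$random_intercept) V <- V + p$sigma0^2
    if (spec$random_slope) V <- V + p$sigma1^2 * tcrossprod(s$n_rate_kg_ha)
    R <- chol(V)
    z <- backsolve(R, s$n2o_kg_n_ha_yr - mu, transpose = TRUE)
    ll <- ll - 0.5 * (nrow(s) * log(2 * pi) + 2 * sum(log(diag(R))) +
                        sum(z^2))
  }
  ll
}

# a minimal fit-shaped object for functions that only read spec/aic/bic
pseudo_fit <- function(name, aic, bic) {
  structure(list(spec = model_spec(name), aic = aic, bic = bic),
            class = "n2o_fit")
}

# a degenerate posterior whose draws are all identical (for DIC / band
# edge cases)
degenerate_posterior <- function(spec, params, a0, a1, n_draws = 20) {
  G <- length(a0)
  chain <- list(
    params = matrix(rep(c(params$mu0, params$mu1, params$sigma0,
                          params$sigma1, params$tau), each = n_draws),
                    n_draws, 5,
                    dimnames = list(NULL, c("mu0", "mu1", "sigma0",
                                            "sigma1", "tau"))),
    a0 = matrix(rep(a0, each = n_draws), n_draws, G),
    a1 = matrix(rep(a1, each = n_draws), n_draws, G)
  )
  structure(
    list(spec = model_spec(spec), priors = prior_spec(),
         chains = list(chain, chain), n_chains = 2L,
         n_iter = n_draws * 2L, n_burnin = n_draws, thin = 1L, seed = 1L,
         psrf = NULL, acceptance = NULL, publication_ids = character(G)),
    class = "n2o_posterior"
  )
}
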