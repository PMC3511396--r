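# Bayesian estimation of the two-random-effect structures. The sampler is
# Metropolis-within-Gibbs: Gaussian random-walk updates for mu0, mu1 and
# the log-transformed SDs (with Jacobian), and a blocked joint update of
# each publication's (a0_i, a1_i) pair, vectorized across publications.
# Proposal scales adapt toward standard acceptance targets during burn-in
# only, so the post-burn-in chain is a fixed-kernel Markov chain.

#' Prior specification for the Bayesian models
#'
#' Vague priors: `mu0, mu1 ~ N(0, 1000)` (variance 1000, so prior SD
#' `sqrt(1000) ~ 31.6`, conventionally reported as 32) and
#' `tau, sigma0, sigma1 ~ U(0, 100)`.
#'
#' @param mu_mean,mu_var Normal prior mean and *variance* for `mu0`, `mu1`.
#' @param sd_upper Upper bound of the uniform priors on the SDs.
#' @return An object of class `"prior_spec"`.
#' @export
prior_spec <- function(mu_mean = 0, mu_var = 1000, sd_upper = 100) {
  stopifnot(mu_var > 0, sd_upper > 0)
  structure(list(mu_mean = mu_mean, mu_var = mu_var, sd_upper = sd_upper),
            class = "prior_spec")
}

# conditional per-observation log-density given latents
cond_ll_obs <- function(linear, mu0, mu1, a0g, a1g, tau, x, y) {
  eta <- mu0 + a0g + (mu1 + a1g) * x
  m <- if (linear) eta else exp(eta)
  stats::dnorm(y, m, tau, log = TRUE)
}

#' Joint log-posterior density (up to a constant)
#'
#' Conditional data log-likelihood given the latent publication effects,
#' plus the latent Gaussian log-density, plus the prior log-density of the
#' population parameters. Returns `-Inf` outside the prior support
#' (`tau`, `sigma0`, `sigma1` must lie in `(0, sd_upper)`).
#'
#' @param spec Bayesian model name or [model_spec()] (`NL-N-RR-B` or
#'   `L-N-RR-B`).
#' @param params A [param_set()] on the natural scale.
#' @param latents List with numeric vectors `a0` and `a1`, one entry per
#'   publication in order of first appearance in `data`.
#' @param data Emission tibble.
#' @param priors A [prior_spec()].
#' @return Scalar log-density.
#' @export
log_posterior <- function(spec, params, latents, data, priors = prior_spec()) {
  spec <- as_model_spec(spec)
  d <- data_index(data)
  if (length(latents$a0) != d$G || length(latents$a1) != d$G) {
    stop("latents must have one a0 and one a1 per publication (", d$G, ")",
         call. = FALSE)
  }
  sds <- c(params$tau, params$sigma0, params$sigma1)
  if (any(sds <= 0) || any(sds >= priors$sd_upper)) return(-Inf)
  ll <- sum(cond_ll_obs(spec$linear, params$mu0, params$mu1,
                        latents$a0[d$g], latents$a1[d$g], params$tau,
                        d$x, d$y))
  lat <- sum(stats::dnorm(latents$a0, 0, params$sigma0, log = TRUE)) +
    sum(stats::dnorm(latents$a1, 0, params$sigma1, log = TRUE))
  pri <- stats::dnorm(params$mu0, priors$mu_mean, sqrt(priors$mu_var), log = TRUE) +
    stats::dnorm(params$mu1, priors$mu_mean, sqrt(priors$mu_var), log = TRUE) +
    3 * log(1 / priors$sd_upper)
  ll + lat + pri
}

#' Run the MCMC sampler for a Bayesian emission model
#'
#' Samples the posterior of `NL-N-RR-B` or `L-N-RR-B` (exponential or
#' linear mean, random intercept and random N effect) under
#' [prior_spec()] priors. Chains are initialized overdispersed from
#' distinct seed streams derived from `seed`, and runs are bit-reproducible
#' for a given seed and configuration.
#'
#' @param spec `"NL-N-RR-B"` or `"L-N-RR-B"`.
#' @param data Emission tibble; may have zero rows, in which case the
#'   posterior is the prior.
#' @param priors A [prior_spec()].
#' @param n_chains Number of chains (>= 2 for convergence diagnostics).
#' @param n_iter Iterations per chain.
#' @param n_burnin Burn-in iterations discarded (default half).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed.
#' @return An object of class `"n2o_posterior"`: per-chain draw matrices of
#'   `(mu0, mu1, sigma0, sigma1, tau)` and of the latent effects, the
#'   per-parameter Gelman-Rubin statistic (`psrf`), and post-adaptation
#'   acceptance rates. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @seealso [dic()], [credibility_band()], [gelman_rubin()]
#' @export
run_mcmc <- function(spec, data, priors = prior_spec(), n_chains = 3,
                     n_iter = 20000, n_burnin = floor(n_iter / 2),
                     thin = 10, seed = 1) {
  spec <- as_model_spec(spec)
  if (!spec$bayesian) {
    stop("run_mcmc() is for the Bayesian models NL-N-RR-B / L-N-RR-B",
         call. = FALSE)
  }
  stopifnot(n_iter > n_burnin, n_chains >= 1, thin >= 1)
  d <- if (nrow(data) > 0) data_index(data) else
    list(g = integer(0), G = 0L, ids = character(0),
         x = numeric(0), y = numeric(0), n = 0L)
  linear <- spec$linear
  sdu <- priors$sd_upper
  musd <- sqrt(priors$mu_var)
  keep_iters <- seq(n_burnin + thin, n_iter, by = thin)
  comp_names <- c("mu0", "mu1", "log_sigma0", "log_sigma1", "log_tau",
                  "latent", "shift0", "shift1", "scale0", "scale1")

  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed((seed + 104729 * ch) %% 2147483647L)
    mu0 <- stats::rnorm(1, 0, if (linear) 2 else 1)
    mu1 <- stats::rnorm(1, 0, 0.01)
    s0 <- stats::runif(1, 0.2, 3)
    s1 <- stats::runif(1, 0.001, 0.02)
    tau <- stats::runif(1, 0.5, 5)
    a0 <- stats::rnorm(d$G, 0, s0)
    a1 <- stats::rnorm(d$G, 0, s1)

    ll_obs <- cond_ll_obs(linear, mu0, mu1, a0[d$g], a1[d$g], tau, d$x, d$y)
    ll <- sum(ll_obs)
    scale <- c(mu0 = 0.2, mu1 = 0.002, log_sigma0 = 0.3, log_sigma1 = 0.3,
               log_tau = 0.2, a0 = 0.4, a1 = 0.004,
               shift0 = 0.2, shift1 = 0.002, scale0 = 0.3, scale1 = 0.3)
    acc <- stats::setNames(numeric(length(comp_names)), comp_names)
    prop <- stats::setNames(numeric(length(comp_names)), comp_names)
    acc_win <- stats::setNames(numeric(length(scale)), names(scale))
    prop_win <- stats::setNames(numeric(length(scale)), names(scale))

    n_keep <- length(keep_iters)
    par_draws <- matrix(NA_real_, n_keep, 5,
                        dimnames = list(NULL, c("mu0", "mu1", "sigma0",
                                                "sigma1", "tau")))
    a0_draws <- matrix(NA_real_, n_keep, d$G)
    a1_draws <- matrix(NA_real_, n_keep, d$G)
    kk <- 0L

    for (it in seq_len(n_iter)) {
      in_burn <- it <= n_burnin

      # mu0 and mu1: random walk on the mean parameters
      for (pm in c("mu0", "mu1")) {
        cur <- if (pm == "mu0") mu0 else mu1
        cand <- cur + scale[[pm]] * stats::rnorm(1)
        ll_new <- sum(cond_ll_obs(linear,
                                  if (pm == "mu0") cand else mu0,
                                  if (pm == "mu1") cand else mu1,
                                  a0[d$g], a1[d$g], tau, d$x, d$y))
        lr <- ll_new - ll +
          stats::dnorm(cand, priors$mu_mean, musd, log = TRUE) -
          stats::dnorm(cur, priors$mu_mean, musd, log = TRUE)
        prop_win[[pm]] <- prop_win[[pm]] + 1
        if (!in_burn) prop[[pm]] <- prop[[pm]] + 1
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          if (pm == "mu0") mu0 <- cand else mu1 <- cand
          ll <- ll_new
          acc_win[[pm]] <- acc_win[[pm]] + 1
          if (!in_burn) acc[[pm]] <- acc[[pm]] + 1
        }
      }

      # log tau: affects the data term only (plus uniform prior + Jacobian)
      lt <- log(tau)
      cand <- lt + scale[["log_tau"]] * stats::rnorm(1)
      prop_win[["log_tau"]] <- prop_win[["log_tau"]] + 1
      if (!in_burn) prop[["log_tau"]] <- prop[["log_tau"]] + 1
      if (exp(cand) < sdu) {
        ll_new <- sum(cond_ll_obs(linear, mu0, mu1, a0[d$g], a1[d$g],
                                  exp(cand), d$x, d$y))
        lr <- ll_new - ll + cand - lt  # Jacobian of sigma = exp(l)
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          tau <- exp(cand)
          ll <- ll_new
          acc_win[["log_tau"]] <- acc_win[["log_tau"]] + 1
          if (!in_burn) acc[["log_tau"]] <- acc[["log_tau"]] + 1
        }
      }

      # log sigma0 / sigma1: latent prior terms only
      for (ls in c("log_sigma0", "log_sigma1")) {
        cur_s <- if (ls == "log_sigma0") s0 else s1
        lat <- if (ls == "log_sigma0") a0 else a1
        l <- log(cur_s)
        cand <- l + scale[[ls]] * stats::rnorm(1)
        prop_win[[ls]] <- prop_win[[ls]] + 1
        if (!in_burn) prop[[ls]] <- prop[[ls]] + 1
        if (exp(cand) < sdu) {
          lr <- sum(stats::dnorm(lat, 0, exp(cand), log = TRUE)) -
            sum(stats::dnorm(lat, 0, cur_s, log = TRUE)) + cand - l
          if (is.finite(lr) && log(stats::runif(1)) < lr) {
            if (ls == "log_sigma0") s0 <- exp(cand) else s1 <- exp(cand)
            acc_win[[ls]] <- acc_win[[ls]] + 1
            if (!in_burn) acc[[ls]] <- acc[[ls]] + 1
          }
        }
      }

      # blocked latent update: joint (a0_i, a1_i) proposal per publication
      if (d$G > 0) {
        a0c <- a0 + scale[["a0"]] * stats::rnorm(d$G)
        a1c <- a1 + scale[["a1"]] * stats::rnorm(d$G)
        ll_obs_cur <- cond_ll_obs(linear, mu0, mu1, a0[d$g], a1[d$g],
                                  tau, d$x, d$y)
        ll_obs_new <- cond_ll_obs(linear, mu0, mu1, a0c[d$g], a1c[d$g],
                                  tau, d$x, d$y)
        dgrp <- group_sum(ll_obs_new - ll_obs_cur, d$g, d$G) +
          stats::dnorm(a0c, 0, s0, log = TRUE) -
          stats::dnorm(a0, 0, s0, log = TRUE) +
          stats::dnorm(a1c, 0, s1, log = TRUE) -
          stats::dnorm(a1, 0, s1, log = TRUE)
        accept <- is.finite(dgrp) & log(stats::runif(d$G)) < dgrp
        a0[accept] <- a0c[accept]
        a1[accept] <- a1c[accept]
        ll <- sum(cond_ll_obs(linear, mu0, mu1, a0[d$g], a1[d$g], tau,
                              d$x, d$y))
        prop_win[["a0"]] <- prop_win[["a0"]] + 1
        acc_win[["a0"]] <- acc_win[["a0"]] + mean(accept)
        if (!in_burn) {
          prop[["latent"]] <- prop[["latent"]] + 1
          acc[["latent"]] <- acc[["latent"]] + mean(accept)
        }
      }

      # translation moves: shift mu against the latents (likelihood
      # invariant, only prior terms change) - decorrelates mu from a
      if (d$G > 0) {
        for (sh in c("shift0", "shift1")) {
          delta <- scale[[sh]] * stats::rnorm(1)
          if (sh == "shift0") {
            mu_cur <- mu0; lat <- a0; s_lat <- s0
          } else {
            mu_cur <- mu1; lat <- a1; s_lat <- s1
          }
          lr <- stats::dnorm(mu_cur + delta, priors$mu_mean, musd, log = TRUE) -
            stats::dnorm(mu_cur, priors$mu_mean, musd, log = TRUE) +
            sum(stats::dnorm(lat - delta, 0, s_lat, log = TRUE)) -
            sum(stats::dnorm(lat, 0, s_lat, log = TRUE))
          prop_win[[sh]] <- prop_win[[sh]] + 1
          if (!in_burn) prop[[sh]] <- prop[[sh]] + 1
          if (is.finite(lr) && log(stats::runif(1)) < lr) {
            if (sh == "shift0") {
              mu0 <- mu0 + delta; a0 <- a0 - delta
            } else {
              mu1 <- mu1 + delta; a1 <- a1 - delta
            }
            acc_win[[sh]] <- acc_win[[sh]] + 1
            if (!in_burn) acc[[sh]] <- acc[[sh]] + 1
          }
        }

        # group scale moves: rescale (sigma, a) jointly - decorrelates the
        # between-publication SD from the latent spread. With c = exp(eps)
        # the latent prior terms cancel, leaving the data term + log c.
        for (sc in c("scale0", "scale1")) {
          cc <- exp(scale[[sc]] * stats::rnorm(1))
          s_new <- if (sc == "scale0") s0 * cc else s1 * cc
          prop_win[[sc]] <- prop_win[[sc]] + 1
          if (!in_burn) prop[[sc]] <- prop[[sc]] + 1
          if (s_new < sdu) {
            a0c <- if (sc == "scale0") a0 * cc else a0
            a1c <- if (sc == "scale1") a1 * cc else a1
            ll_new <- sum(cond_ll_obs(linear, mu0, mu1, a0c[d$g], a1c[d$g],
                                      tau, d$x, d$y))
            lr <- ll_new - ll + log(cc)
            if (is.finite(lr) && log(stats::runif(1)) < lr) {
              if (sc == "scale0") {
                s0 <- s_new; a0 <- a0c
              } else {
                s1 <- s_new; a1 <- a1c
              }
              ll <- ll_new
              acc_win[[sc]] <- acc_win[[sc]] + 1
              if (!in_burn) acc[[sc]] <- acc[[sc]] + 1
            }
          }
        }
      }

      # burn-in-only adaptation toward standard acceptance targets
      if (in_burn && it %% 50 == 0) {
        for (nm in names(scale)) {
          key <- if (nm == "a1") "a0" else nm  # latent pair shares its rate
          if (prop_win[[key]] > 0) {
            rate <- acc_win[[key]] / prop_win[[key]]
            target <- if (nm %in% c("a0", "a1")) 0.3 else 0.44
            scale[[nm]] <- min(max(scale[[nm]] * exp(0.7 * (rate - target)),
                                   1e-7), 200)
          }
        }
        acc_win[] <- 0
        prop_win[] <- 0
      }

      if (!in_burn && (it - n_burnin) %% thin == 0) {
        kk <- kk + 1L
        par_draws[kk, ] <- c(mu0, mu1, s0, s1, tau)
        if (d$G > 0) {
          a0_draws[kk, ] <- a0
          a1_draws[kk, ] <- a1
        }
      }
    }
    chains[[ch]] <- list(params = par_draws, a0 = a0_draws, a1 = a1_draws,
                         accept = ifelse(prop > 0, acc / prop, NA_real_),
                         scale = scale)
  }

  rates <- purrr::map(chains, "accept")
  mean_rates <- Reduce(`+`, rates) / n_chains
  out_of_range <- mean_rates[!is.na(mean_rates) &
                               (mean_rates < 0.05 | mean_rates > 0.95)]
  if (length(out_of_range)) {
    warning("post-adaptation acceptance rate outside (0.05, 0.95) for: ",
            paste(names(out_of_range), collapse = ", "), call. = FALSE)
  }

  psrf <- if (n_chains >= 2) {
    vapply(c("mu0", "mu1", "sigma0", "sigma1", "tau"), function(pm) {
      gelman_rubin(vapply(chains, function(c) c$params[, pm],
                          numeric(nrow(chains[[1]]$params))))
    }, numeric(1))
  } else {
    stats::setNames(rep(NA_real_, 5),
                    c("mu0", "mu1", "sigma0", "sigma1", "tau"))
  }

  structure(
    list(spec = spec, priors = priors, chains = chains,
         n_chains = n_chains, n_iter = n_iter, n_burnin = n_burnin,
         thin = thin, seed = seed, psrf = psrf,
         acceptance = mean_rates, publication_ids = d$ids),
    class = "n2o_posterior"
  )
}

#' Stacked posterior draws
#'
#' @param sample An `n2o_posterior`.
#' @param what `"params"` (default), `"a0"` or `"a1"`.
#' @return A matrix with all chains' kept draws stacked row-wise.
#' @export
posterior_draws <- function(sample, what = c("params", "a0", "a1")) {
  what <- match.arg(what)
  do.call(rbind, purrr::map(sample$chains, what))
}

#' @export
print.n2o_posterior <- function(x, ...) {
  cat("<n2o_posterior> ", x$spec$name, ": ", x$n_chains, " chains x ",
      x$n_iter, " iterations (burn-in ", x$n_burnin, ", thin ", x$thin,
      ")\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @method tidy n2o_posterior
#' @export
tidy.n2o_posterior <- function(x, ...) {
  dr <- posterior_draws(x)
  tibble::tibble(
    term = colnames(dr),
    estimate = colMeans(dr),
    std.error = apply(dr, 2, stats::sd),
    conf.low = apply(dr, 2, stats::quantile, 0.025),
    conf.high = apply(dr, 2, stats::quantile, 0.975),
    psrf = unname(x$psrf[colnames(dr)])
  )
}

#' @method glance n2o_posterior
#' @export
glance.n2o_posterior <- function(x, ...) {
  tibble::tibble(
    model = x$spec$name, n_chains = x$n_chains, n_iter = x$n_iter,
    n_burnin = x$n_burnin, thin = x$thin,
    n_draws = nrow(posterior_draws(x)),
    max_psrf = if (all(is.na(x$psrf))) NA_real_ else max(x$psrf, na.rm = TRUE)
  )
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computed from the between- and within-chain variances of the second
#' half of each chain. The raw estimator can fall below 1 by order `1/n`
#' when chains agree; since values below 1 carry no diagnostic meaning the
#' statistic is clamped below at 1, so identical chains give exactly 1.
#'
#' @param chains A matrix with one column per chain, or a list of
#'   equal-length numeric vectors (>= 2 chains, >= 10 kept draws each).
#' @return Scalar PSRF (>= 1). Values below ~1.1 conventionally indicate
#'   convergence.
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  if (is.null(dim(chains)) || ncol(chains) < 2) {
    stop("need at least 2 chains", call. = FALSE)
  }
  n_full <- nrow(chains)
  if (n_full < 10) stop("chains too short (need >= 10 draws)", call. = FALSE)
  half <- chains[(floor(n_full / 2) + 1):n_full, , drop = FALSE]
  n <- nrow(half)
  m <- ncol(half)
  means <- colMeans(half)
  W <- mean(apply(half, 2, stats::var))
  B_over_n <- stats::var(means)  # = B/n
  if (W == 0) return(if (B_over_n == 0) 1 else Inf)
  v <- ((n - 1) / n * W + B_over_n) / W
  sqrt(max(v, 1))
}

#' Deviance information criterion
#'
#' `DIC = Dbar + pD` with `pD = Dbar - D(theta_bar)`, where the deviance
#' is `-2` times the *conditional* data log-likelihood given the latent
#' publication effects (the convention of mainstream Gibbs-sampling
#' software; conditioning changes `pD`, so the convention matters when
#' comparing across tools), and `theta_bar` plugs in the posterior means
#' of both the population parameters and the latents.
#'
#' @param sample An `n2o_posterior`.
#' @param data The emission tibble the sample was fitted to.
#' @return Scalar DIC (lower is better).
#' @export
dic <- function(sample, data) {
  spec <- sample$spec
  d <- data_index(data)
  pars <- posterior_draws(sample, "params")
  a0 <- posterior_draws(sample, "a0")
  a1 <- posterior_draws(sample, "a1")
  dev <- vapply(seq_len(nrow(pars)), function(i) {
    -2 * sum(cond_ll_obs(spec$linear, pars[i, "mu0"], pars[i, "mu1"],
                         a0[i, d$g], a1[i, d$g], pars[i, "tau"], d$x, d$y))
  }, numeric(1))
  dbar <- mean(dev)
  d_at_mean <- -2 * sum(cond_ll_obs(spec$linear, mean(pars[, "mu0"]),
                                    mean(pars[, "mu1"]),
                                    colMeans(a0)[d$g], colMeans(a1)[d$g],
                                    mean(pars[, "tau"]), d$x, d$y))
  dbar + (dbar - d_at_mean)
}

#' Credibility band for predicted emissions
#'
#' Pushes each kept posterior draw of `(mu0, mu1)` through the
#' population-level mean response on a dose grid and takes pointwise
#' 2.5/97.5 percentiles; the point curve is the pointwise median. With
#' `subtract_background = TRUE` each draw's dose-0 prediction is
#' subtracted first, giving emission due to applied N.
#'
#' @param sample An `n2o_posterior`.
#' @param dose_grid Numeric vector of doses (non-empty).
#' @param subtract_background Subtract each draw's dose-0 value.
#' @return An uncertainty-band tibble (class `"n2o_band"`) with columns
#'   `model`, `dose`, `point`, `lower`, `upper`.
#' @export
credibility_band <- function(sample, dose_grid = seq(0, 500, by = 5),
                             subtract_background = TRUE) {
  if (length(dose_grid) == 0) stop("empty dose grid", call. = FALSE)
  pars <- posterior_draws(sample, "params")
  linear <- sample$spec$linear
  eta <- outer(pars[, "mu1"], dose_grid) + pars[, "mu0"]
  pred <- if (linear) eta else exp(eta)
  if (subtract_background) {
    bg <- if (linear) pars[, "mu0"] else exp(pars[, "mu0"])
    pred <- pred - bg
  }
  new_band(
    model = sample$spec$name, dose = dose_grid,
    point = apply(pred, 2, stats::median),
    lower = apply(pred, 2, stats::quantile, 0.025),
    upper = apply(pred, 2, stats::quantile, 0.975),
    background_subtracted = subtract_background,
    provenance = list(method = "posterior", n_draws = nrow(pars),
                      seed = sample$seed)
  )
}
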