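# Approximate maximum-likelihood estimation. Variance parameters are
# optimized on the log scale to enforce positivity; standard errors of the
# fixed effects come from the inverse observed information at the optimum.

par_layout <- function(spec) {
  nm <- "mu0"
  if (spec$uses_N) nm <- c(nm, "mu1")
  if (spec$random_intercept) nm <- c(nm, "log_sigma0")
  if (spec$random_slope) nm <- c(nm, "log_sigma1")
  c(nm, "log_tau")
}

theta_to_params <- function(spec, theta) {
  nm <- par_layout(spec)
  v <- stats::setNames(theta, nm)
  param_set(
    mu0 = v[["mu0"]],
    mu1 = if (spec$uses_N) v[["mu1"]] else NA_real_,
    sigma0 = if (spec$random_intercept) exp(v[["log_sigma0"]]) else 0,
    sigma1 = if (spec$random_slope) exp(v[["log_sigma1"]]) else 0,
    tau = exp(v[["log_tau"]])
  )
}

n_free_params <- function(spec) {
  2L + spec$uses_N + spec$random_intercept + spec$random_slope
}

default_init <- function(spec, data) {
  x <- data$n_rate_kg_ha
  y <- data$n2o_kg_n_ha_yr
  if (spec$linear) {
    fit <- if (spec$uses_N) stats::lm(y ~ x) else stats::lm(y ~ 1)
    mu0 <- unname(stats::coef(fit)[1])
    mu1 <- if (spec$uses_N) unname(stats::coef(fit)[2]) else NA_real_
    res_sd <- stats::sd(stats::resid(fit))
    s0 <- max(res_sd * 0.5, 1e-3)
    s1 <- if (spec$uses_N) max(abs(mu1) * 0.5, 1e-4) else 0
  } else {
    ylog <- log(pmax(y, 0.05))
    fit <- if (spec$uses_N) stats::lm(ylog ~ x) else stats::lm(ylog ~ 1)
    mu0 <- unname(stats::coef(fit)[1])
    mu1 <- if (spec$uses_N) unname(stats::coef(fit)[2]) else NA_real_
    res_sd <- stats::sd(y - exp(stats::fitted(fit)))
    s0 <- 0.5
    s1 <- if (spec$uses_N) max(abs(mu1) * 0.5, 1e-4) else 0
  }
  param_set(
    mu0 = mu0, mu1 = mu1,
    sigma0 = if (spec$random_intercept) s0 else 0,
    sigma1 = if (spec$random_slope) s1 else 0,
    tau = max(res_sd, 1e-3)
  )
}

params_to_theta <- function(spec, params) {
  th <- params$mu0
  if (spec$uses_N) th <- c(th, params$mu1)
  if (spec$random_intercept) th <- c(th, log(max(params$sigma0, 1e-6)))
  if (spec$random_slope) th <- c(th, log(max(params$sigma1, 1e-8)))
  stats::setNames(c(th, log(max(params$tau, 1e-6))), par_layout(spec))
}

# exact MLE for linear fixed-effects-only structures (OLS + ML variance)
fit_linear_fixed <- function(spec, data) {
  x <- data$n_rate_kg_ha
  y <- data$n2o_kg_n_ha_yr
  n <- length(y)
  fit <- if (spec$uses_N) stats::lm(y ~ x) else stats::lm(y ~ 1)
  rss <- sum(stats::resid(fit)^2)
  tau2 <- rss / n
  ll <- -0.5 * n * (log(2 * pi * tau2) + 1)
  cf <- stats::coef(fit)
  xtxinv <- stats::summary.lm(fit)$cov.unscaled
  se <- sqrt(diag(tau2 * xtxinv))
  list(
    params = param_set(mu0 = unname(cf[1]),
                       mu1 = if (spec$uses_N) unname(cf[2]) else NA_real_,
                       tau = sqrt(tau2)),
    se = c(mu0 = unname(se[1]),
           mu1 = if (spec$uses_N) unname(se[2]) else NA_real_),
    loglik = ll, converged = TRUE, boundary = FALSE,
    trace = list(method = "closed-form OLS MLE")
  )
}

#' Fit an emission model by approximate maximum likelihood
#'
#' Maximizes the marginal log-likelihood ([loglik_linear_mixed()] for
#' linear structures, [loglik_nonlinear_mixed()] for exponential ones)
#' over `(mu0, mu1, log sigma0, log sigma1, log tau)` with BFGS. Linear
#' structures without random effects use the exact closed-form MLE.
#' Standard errors for `mu0` and `mu1` are taken from the inverse observed
#' information. Variance estimates that collapse below `exp(-10)` are
#' reported as 0 with a boundary flag. Non-convergence is reported in the
#' result (`converged = FALSE`), not thrown.
#'
#' @param spec Non-Bayesian model name or [model_spec()].
#' @param data Emission tibble; random-effect structures need at least two
#'   publications.
#' @param init Optional [param_set()] of starting values.
#' @param n_nodes Quadrature nodes per dimension for exponential
#'   structures.
#' @param control Passed to [stats::optim()] (entries `maxit`, `reltol`);
#'   set `control$force_optim = TRUE` to route the closed-form cases
#'   through the optimizer (used for verification).
#' @return An object of class `"n2o_fit"`: list with `spec`, `estimates`
#'   ([param_set()]), `se`, `loglik`, `n_obs`, `n_params`, `aic`, `bic`,
#'   `converged`, `boundary`, `trace`. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @examples
#' d <- simulate_emissions("L-N-FF", param_set(1, 0.01, tau = 1),
#'                         design_config(30), seed = 42)
#' fit <- fit_ml("L-N-FF", d)
#' glance(fit)
#' @export
fit_ml <- function(spec, data, init = NULL, n_nodes = 9, control = list()) {
  spec <- as_model_spec(spec)
  if (spec$bayesian) stop("use run_mcmc() for Bayesian models", call. = FALSE)
  has_ranef <- spec$random_intercept || spec$random_slope
  if (has_ranef && length(unique(data$publication_id)) < 2L) {
    stop("random-effect models need at least 2 publications", call. = FALSE)
  }
  force_optim <- isTRUE(control$force_optim)
  control$force_optim <- NULL
  n <- nrow(data)
  k <- n_free_params(spec)

  if (spec$linear && !has_ranef && !force_optim) {
    res <- fit_linear_fixed(spec, data)
  } else {
    if (is.null(init)) init <- default_init(spec, data)
    theta0 <- params_to_theta(spec, init)
    negll <- function(theta) {
      p <- theta_to_params(spec, theta)
      ll <- tryCatch({
        if (spec$linear) loglik_linear_mixed(spec, p, data)
        else loglik_nonlinear_mixed(spec, p, data, n_nodes = n_nodes)
      }, error = function(e) -Inf)
      if (!is.finite(ll)) 1e10 else -ll
    }
    scales <- vapply(par_layout(spec), function(nm) {
      switch(nm, mu0 = 0.25, mu1 = 0.002, 0.25)
    }, numeric(1))
    opt <- tryCatch(
      stats::optim(theta0, negll, method = "BFGS",
                   control = utils::modifyList(
                     list(maxit = 300, reltol = 1e-10, parscale = scales),
                     control)),
      error = function(e) NULL
    )
    if (is.null(opt)) {
      res <- list(params = init, se = c(mu0 = NA_real_, mu1 = NA_real_),
                  loglik = NA_real_, converged = FALSE, boundary = FALSE,
                  trace = list(error = "optimizer failure"))
    } else {
      est <- theta_to_params(spec, opt$par)
      nm <- par_layout(spec)
      boundary <- any(opt$par[grep("^log_sigma", nm)] < -10)
      if (boundary) {
        if (spec$random_intercept && opt$par[match("log_sigma0", nm)] < -10) {
          est$sigma0 <- 0
        }
        if (spec$random_slope && opt$par[match("log_sigma1", nm)] < -10) {
          est$sigma1 <- 0
        }
      }
      se <- c(mu0 = NA_real_, mu1 = NA_real_)
      hess <- tryCatch(stats::optimHess(opt$par, negll), error = function(e) NULL)
      if (!is.null(hess)) {
        vc <- tryCatch(solve(hess), error = function(e) NULL)
        if (!is.null(vc)) {
          dg <- diag(vc)
          if (all(dg[nm %in% c("mu0", "mu1")] > 0)) {
            se["mu0"] <- sqrt(dg[match("mu0", nm)])
            if (spec$uses_N) se["mu1"] <- sqrt(dg[match("mu1", nm)])
          }
        }
      }
      res <- list(params = est, se = se, loglik = -opt$value,
                  converged = opt$convergence == 0, boundary = boundary,
                  trace = list(optim = opt[c("convergence", "counts", "message")]))
    }
  }

  structure(
    list(spec = spec, estimates = res$params, se = res$se,
         loglik = res$loglik, n_obs = n, n_params = k,
         aic = -2 * res$loglik + 2 * k,
         bic = -2 * res$loglik + k * log(n),
         converged = res$converged, boundary = res$boundary,
         trace = res$trace),
    class = "n2o_fit"
  )
}

#' @export
print.n2o_fit <- function(x, ...) {
  cat("<n2o_fit> ", x$spec$name,
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  cat("  logLik ", format(x$loglik), "  AIC ", format(x$aic),
      "  BIC ", format(x$bic), "  n ", x$n_obs, "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @method tidy n2o_fit
#' @export
tidy.n2o_fit <- function(x, ...) {
  p <- x$estimates
  terms <- c("mu0", "mu1", "sigma0", "sigma1", "tau")
  est <- c(p$mu0, p$mu1, p$sigma0, p$sigma1, p$tau)
  se <- c(x$se[["mu0"]], x$se[["mu1"]], NA, NA, NA)
  keep <- c(TRUE, x$spec$uses_N, x$spec$random_intercept,
            x$spec$random_slope, TRUE)
  tibble::tibble(term = terms[keep], estimate = est[keep],
                 std.error = se[keep])
}

#' @importFrom generics glance
#' @method glance n2o_fit
#' @export
glance.n2o_fit <- function(x, ...) {
  tibble::tibble(
    model = x$spec$name, logLik = x$loglik, AIC = x$aic, BIC = x$bic,
    nobs = x$n_obs, npar = x$n_params, converged = x$converged,
    boundary = x$boundary
  )
}

#' Model-comparison table with within-family percentage increases
#'
#' Collects AIC and BIC from a set of fitted models and expresses each as
#' a percentage increase over the best (lowest) value within its response
#' family — linear models are compared with the best linear model,
#' exponential models with the best exponential model. Best-in-family rows
#' get 0.
#'
#' @param fits List of `n2o_fit` objects (at least one per family for the
#'   percentages to be meaningful).
#' @return A tibble with columns `name`, `linear`, `aic`, `pct_aic`,
#'   `bic`, `pct_bic`, sorted as given.
#' @export
model_selection_table <- function(fits) {
  tab <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(name = f$spec$name, linear = f$spec$linear,
                   aic = f$aic, bic = f$bic)
  })
  if (anyDuplicated(tab$name)) {
    stop("duplicate model names in fits", call. = FALSE)
  }
  tab |>
    dplyr::group_by(.data$linear) |>
    dplyr::mutate(
      pct_aic = 100 * (.data$aic / min(.data$aic) - 1),
      pct_bic = 100 * (.data$bic / min(.data$bic) - 1)
    ) |>
    dplyr::ungroup() |>
    dplyr::relocate("name", "linear", "aic", "pct_aic", "bic", "pct_bic")
}
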