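# Uncertainty bands, the multi-model ensemble range, and the IPCC-Tier 1
# comparison.

new_band <- function(model, dose, point, lower, upper,
                     background_subtracted, provenance) {
  out <- tibble::tibble(model = model, dose = dose, point = point,
                        lower = lower, upper = upper)
  class(out) <- c("n2o_band", class(out))
  attr(out, "background_subtracted") <- background_subtracted
  attr(out, "provenance") <- provenance
  out
}

#' Cluster-bootstrap confidence band for predicted emissions
#'
#' Resamples the data with replacement `B` times, refits the model on each
#' resample, and takes pointwise 2.5/97.5 percentiles of the refitted
#' predictions over a dose grid; the point curve is the pointwise median
#' of the same prediction ensemble. The default resampling unit is the
#' publication (cluster bootstrap): whole publications are drawn with
#' replacement and duplicates relabelled as distinct groups, which
#' respects the within-publication correlation that the mixed models rely
#' on. Observation-level resampling is available via `resample_unit` but
#' breaks the grouping structure.
#'
#' Resamples whose refit fails or does not converge are dropped and
#' counted; more than 10% failures is an error.
#'
#' @param spec Non-Bayesian model name or [model_spec()].
#' @param data Emission tibble.
#' @param B Number of bootstrap resamples.
#' @param dose_grid Dose grid, kg N ha^-1.
#' @param seed Integer seed; bands are bit-reproducible given it.
#' @param resample_unit `"publication"` (default) or `"observation"`.
#' @param subtract_background Band for emission due to N (default) or for
#'   total emission.
#' @param n_nodes Quadrature nodes for exponential structures.
#' @return An uncertainty-band tibble (class `"n2o_band"`) with columns
#'   `model`, `dose`, `point`, `lower`, `upper`; the number of failed
#'   refits is in `attr(, "provenance")`.
#' @export
bootstrap_band <- function(spec, data, B = 500,
                           dose_grid = seq(0, 500, by = 5), seed = 1,
                           resample_unit = c("publication", "observation"),
                           subtract_background = TRUE, n_nodes = 9) {
  spec <- as_model_spec(spec)
  if (spec$bayesian) {
    stop("use credibility_band() for Bayesian models", call. = FALSE)
  }
  resample_unit <- match.arg(resample_unit)
  set.seed(seed)
  full_fit <- fit_ml(spec, data, n_nodes = n_nodes)
  init <- if (full_fit$converged) full_fit$estimates else NULL
  pubs <- unique(data$publication_id)
  pub_rows <- split(seq_len(nrow(data)), data$publication_id)[pubs]

  preds <- matrix(NA_real_, B, length(dose_grid))
  n_failed <- 0L
  for (b in seq_len(B)) {
    if (resample_unit == "publication") {
      take <- sample(pubs, length(pubs), replace = TRUE)
      rows <- pub_rows[take]
      bdata <- data[unlist(rows), ]
      # duplicates become distinct groups (standard cluster bootstrap)
      bdata$publication_id <- rep(paste0(take, "#", seq_along(take)),
                                  lengths(rows))
    } else {
      bdata <- data[sample(nrow(data), nrow(data), replace = TRUE), ]
    }
    fit <- tryCatch(fit_ml(spec, bdata, init = init, n_nodes = n_nodes),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      n_failed <- n_failed + 1L
      next
    }
    p <- if (subtract_background && spec$uses_N) {
      emission_due_to_n(spec, fit$estimates, dose_grid)
    } else {
      mean_response(spec, fit$estimates, dose_grid)
    }
    preds[b, ] <- p
  }
  if (n_failed > 0.1 * B) {
    stop("bootstrap failed: ", n_failed, " of ", B, " refits dropped",
         call. = FALSE)
  }
  ok <- stats::complete.cases(preds)
  new_band(
    model = spec$name, dose = dose_grid,
    point = apply(preds[ok, , drop = FALSE], 2, stats::median),
    lower = apply(preds[ok, , drop = FALSE], 2, stats::quantile, 0.025),
    upper = apply(preds[ok, , drop = FALSE], 2, stats::quantile, 0.975),
    background_subtracted = subtract_background,
    provenance = list(method = "bootstrap", B = B, seed = seed,
                      n_failed = n_failed, resample_unit = resample_unit)
  )
}

#' Select the model ensemble by AIC/BIC proximity to the family best
#'
#' Keeps every non-Bayesian model whose AIC *and* BIC are within
#' `threshold` (default 10%) of the best value in its response family
#' (linear or exponential), then appends the two Bayesian counterparts.
#' On the published reference statistics this selects the six
#' random-effect dose-response models plus the two Bayesian models —
#' an eight-member ensemble.
#'
#' @param fits List of `n2o_fit` objects (typically all 11 non-Bayesian
#'   models).
#' @param threshold Maximum fractional increase over the family best.
#' @return Character vector of selected model names.
#' @export
select_ensemble <- function(fits, threshold = 0.10) {
  tab <- model_selection_table(fits)
  keep <- tab$name[tab$pct_aic <= 100 * threshold &
                     tab$pct_bic <= 100 * threshold]
  if (length(keep) == 0) stop("no models selected", call. = FALSE)
  c(keep, "NL-N-RR-B", "L-N-RR-B")
}

#' Best-case/worst-case ensemble uncertainty range
#'
#' Combines the uncertainty bands of the selected models into a pointwise
#' envelope: `equation range` is the spread of the member point
#' predictions (uncertainty in model equations), and `full range` is the
#' pointwise minimum of the member lower limits and maximum of the member
#' upper limits (equations plus parameter uncertainty) — interpretable as
#' best-case and worst-case emission scenarios.
#'
#' @param bands List of `n2o_band` tibbles on a common dose grid, all
#'   background-subtracted or all not.
#' @return A tibble of class `"n2o_ensemble"` with columns `dose`,
#'   `eq_low`, `eq_high`, `lower`, `upper`.
#' @export
ensemble_range <- function(bands) {
  if (length(bands) == 0) stop("no bands supplied", call. = FALSE)
  grid <- bands[[1]]$dose
  for (b in bands) {
    if (length(b$dose) != length(grid) || any(b$dose != grid)) {
      stop("bands are not on a common dose grid", call. = FALSE)
    }
  }
  pts <- vapply(bands, function(b) b$point, numeric(length(grid)))
  lo <- vapply(bands, function(b) b$lower, numeric(length(grid)))
  hi <- vapply(bands, function(b) b$upper, numeric(length(grid)))
  dim(pts) <- dim(lo) <- dim(hi) <- c(length(grid), length(bands))
  out <- tibble::tibble(
    dose = grid,
    eq_low = apply(pts, 1, min), eq_high = apply(pts, 1, max),
    lower = apply(lo, 1, min), upper = apply(hi, 1, max)
  )
  class(out) <- c("n2o_ensemble", class(out))
  attr(out, "members") <- vapply(bands, function(b) b$model[1], character(1))
  out
}

#' Compare an ensemble range with the IPCC-Tier 1 uncertainty range
#'
#' For each dose in the ensemble grid, reports the ensemble limits next to
#' the IPCC-Tier 1 point estimate (`0.01 * dose`) and uncertainty range
#' (`0.003` to `0.03` times dose), and flags (a) whether the Tier 1 line
#' lies inside the ensemble equation range and (b) whether the full
#' ensemble range is contained in the IPCC range. The ensemble must be
#' background-subtracted, since Tier 1 models emission due to N only.
#'
#' @param ensemble An `"n2o_ensemble"` from [ensemble_range()].
#' @param ef,ef_low,ef_high Tier 1 emission factor and its range.
#' @return A tibble with one row per dose.
#' @export
compare_with_ipcc <- function(ensemble, ef = 0.01, ef_low = 0.003,
                              ef_high = 0.03) {
  ipcc <- ipcc_range(ensemble$dose, ef, ef_low, ef_high)
  tibble::tibble(
    dose = ensemble$dose,
    ens_eq_low = ensemble$eq_low, ens_eq_high = ensemble$eq_high,
    ens_low = ensemble$lower, ens_high = ensemble$upper,
    ipcc_low = ipcc$low, ipcc_point = ipcc$point, ipcc_high = ipcc$high,
    ipcc_in_equation_range = ensemble$eq_low <= ipcc$point &
      ipcc$point <= ensemble$eq_high,
    ensemble_within_ipcc = ensemble$lower >= ipcc$low &
      ensemble$upper <= ipcc$high
  )
}

#' Predictive percentiles of experiment-specific emission
#'
#' Monte-Carlo percentiles of the emission a single (new) experiment would
#' show at a given dose, propagating the between-publication variability:
#' draws of the random effects (and optionally the residual) are pushed
#' through the mean response. This is between-experiment spread, wider
#' than the confidence/credibility bands for the *average* emission.
#'
#' @param spec Model with at least one random component.
#' @param params A [param_set()].
#' @param dose Single dose, kg N ha^-1.
#' @param percentiles Percent levels in (0, 100).
#' @param n_draws Monte-Carlo size.
#' @param include_residual Add the residual term `N(0, tau^2)`.
#' @param subtract_background Subtract each draw's dose-0 emission.
#' @param seed Integer seed.
#' @return A tibble with columns `percentile`, `value`.
#' @export
predictive_percentiles <- function(spec, params, dose,
                                   percentiles = c(90, 95, 99),
                                   n_draws = 1e5,
                                   include_residual = FALSE,
                                   subtract_background = FALSE,
                                   seed = 1) {
  spec <- as_model_spec(spec)
  validate_params(spec, params)
  if (!spec$random_intercept && !spec$random_slope) {
    stop("requires a model with at least one random component", call. = FALSE)
  }
  if (any(percentiles <= 0 | percentiles >= 100)) {
    stop("percentiles must lie strictly between 0 and 100", call. = FALSE)
  }
  stopifnot(length(dose) == 1, n_draws >= 1)
  set.seed(seed)
  a0 <- if (spec$random_intercept) stats::rnorm(n_draws, 0, params$sigma0) else 0
  a1 <- if (spec$random_slope) stats::rnorm(n_draws, 0, params$sigma1) else 0
  y <- mean_response(spec, params, rep(dose, n_draws), a0 = a0, a1 = a1)
  if (subtract_background) {
    y <- y - mean_response(spec, params, rep(0, n_draws), a0 = a0, a1 = a1)
  }
  if (include_residual) y <- y + stats::rnorm(n_draws, 0, params$tau)
  tibble::tibble(
    percentile = percentiles,
    value = unname(stats::quantile(y, percentiles / 100))
  )
}
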