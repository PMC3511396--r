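#' Mean N2O emission response to applied N
#'
#' Evaluates the population or publication-specific mean response of a
#' model structure at one or more doses. Linear models give
#' `(mu0 + a0) + (mu1 + a1) * dose`; exponential models give
#' `exp((mu0 + a0) + (mu1 + a1) * dose)`. Terms a structure excludes
#' (no applied-N effect) are dropped.
#'
#' @param spec Model name or [model_spec()].
#' @param params A [param_set()].
#' @param dose Applied N, kg N ha^-1; vectorized, must be `>= 0`.
#' @param a0,a1 Publication-specific deviations of intercept and N effect
#'   (default 0, the population-level curve). Must be 0 for components the
#'   model treats as fixed.
#' @return Numeric vector of emissions, kg N2O-N ha^-1 yr^-1.
#' @examples
#' mean_response("NL-N-RR", ref_params("NL-N-RR"), dose = c(0, 100))
#' @export
mean_response <- function(spec, params, dose, a0 = 0, a1 = 0) {
  spec <- as_model_spec(spec)
  if (any(dose < 0)) stop("dose must be nonnegative", call. = FALSE)
  if (!spec$random_intercept && any(a0 != 0)) {
    stop("a0 must be 0: model ", spec$name, " has a fixed intercept", call. = FALSE)
  }
  if (!spec$random_slope && any(a1 != 0)) {
    stop("a1 must be 0: model ", spec$name, " has a fixed N effect", call. = FALSE)
  }
  eta <- params$mu0 + a0
  if (spec$uses_N) eta <- eta + (params$mu1 + a1) * dose
  eta <- eta + 0 * dose  # recycle to dose length for dose-free models
  if (spec$linear) eta else exp(eta)
}

#' Emission attributable to applied N
#'
#' The background-subtracted emission `mean_response(dose) -
#' mean_response(0)`, the quantity the IPCC-Tier 1 method models as
#' `EF * dose`. For linear models this is exactly `mu1 * dose`; for
#' exponential models the population-level background `exp(mu0)` (random
#' effects at zero) is subtracted.
#'
#' @inheritParams mean_response
#' @return Numeric vector, kg N2O-N ha^-1 yr^-1.
#' @examples
#' emission_due_to_n("NL-N-RR", ref_params("NL-N-RR"), 100)
#' @export
emission_due_to_n <- function(spec, params, dose) {
  spec <- as_model_spec(spec)
  if (!spec$uses_N) {
    stop("emission due to N is undefined for model ", spec$name,
         " (no applied-N term)", call. = FALSE)
  }
  mean_response(spec, params, dose) - mean_response(spec, params, 0)
}

#' Emission reduction from lowering the N dose
#'
#' @inheritParams mean_response
#' @param dose_from,dose_to Doses in kg N ha^-1 with `dose_from >= dose_to`.
#' @return `mean_response(dose_from) - mean_response(dose_to)`, in
#'   kg N2O-N ha^-1 yr^-1.
#' @examples
#' # lowering 150 -> 120 kg N under the exponential two-random-effect model
#' emission_reduction("NL-N-RR", ref_params("NL-N-RR"), 150, 120)
#' @export
emission_reduction <- function(spec, params, dose_from, dose_to) {
  if (any(dose_from < dose_to)) {
    stop("dose_from must be >= dose_to", call. = FALSE)
  }
  mean_response(spec, params, dose_from) - mean_response(spec, params, dose_to)
}

#' Marginal and average emission factors
#'
#' `marginal_ef()` is the derivative of the mean response with respect to
#' dose: the fraction of one *additional* kg of applied N emitted as
#' N2O-N. It equals `mu1` for linear models (constant) and
#' `mu1 * exp(mu0 + mu1 * dose)` for exponential models (increasing in dose
#' when `mu1 > 0`). `average_ef()` is the IPCC-style ratio
#' `emission_due_to_n(dose) / dose`.
#'
#' @inheritParams mean_response
#' @return Dimensionless fraction(s).
#' @examples
#' marginal_ef("NL-N-RR", ref_params("NL-N-RR"), c(0, 100, 200))
#' average_ef("L-N-RR", ref_params("L-N-RR"), 100)  # == mu1 exactly
#' @export
marginal_ef <- function(spec, params, dose) {
  spec <- as_model_spec(spec)
  if (!spec$uses_N) {
    stop("emission factor undefined for model ", spec$name, call. = FALSE)
  }
  if (any(dose < 0)) stop("dose must be nonnegative", call. = FALSE)
  if (spec$linear) {
    rep_len(params$mu1, length(dose))
  } else {
    params$mu1 * exp(params$mu0 + params$mu1 * dose)
  }
}

#' @rdname marginal_ef
#' @export
average_ef <- function(spec, params, dose) {
  if (any(dose == 0)) {
    stop("average emission factor is undefined at dose 0", call. = FALSE)
  }
  emission_due_to_n(spec, params, dose) / dose
}

#' Dose at which the marginal emission factor reaches a target
#'
#' For exponential models with `mu1 > 0` the marginal emission factor
#' grows with dose, so there is a unique dose at which it crosses any
#' target above its dose-zero value; below that dose the model emits less
#' per marginal kg of N than a constant-EF method using the target. Closed
#' form: `X* = (log(target / mu1) - mu0) / mu1`. With the published
#' reference estimates and the IPCC default target of 1%, the threshold is
#' about 217 kg N ha^-1 (reported to the nearest 10: 220) for the
#' two-random-effect exponential model and about 242 (240) for its
#' random-slope variant.
#'
#' @inheritParams mean_response
#' @param target_ef Target emission factor (fraction), default the IPCC
#'   Tier 1 value 0.01.
#' @return Dose in kg N ha^-1 (not rounded).
#' @examples
#' ef_threshold_dose("NL-N-RR", ref_params("NL-N-RR"))  # ~217.4
#' @export
ef_threshold_dose <- function(spec, params, target_ef = 0.01) {
  spec <- as_model_spec(spec)
  if (spec$linear) {
    stop("threshold dose undefined for linear models: EF is constant", call. = FALSE)
  }
  if (!spec$uses_N || !isTRUE(params$mu1 > 0)) {
    stop("requires an exponential model with mu1 > 0", call. = FALSE)
  }
  ef0 <- marginal_ef(spec, params, 0)
  if (target_ef < ef0) {
    stop("target_ef ", target_ef, " is below the dose-zero marginal EF ",
         signif(ef0, 4), call. = FALSE)
  }
  (log(target_ef / params$mu1) - params$mu0) / params$mu1
}

#' IPCC-Tier 1 emission estimate and uncertainty range
#'
#' The Tier 1 default method estimates direct N2O-N emission due to N
#' inputs as `EF * dose` with `EF = 0.01`, and brackets it with the
#' published EF uncertainty range 0.003 to 0.03.
#'
#' @param dose Applied N, kg N ha^-1 (vectorized, `>= 0`).
#' @param ef Emission factor, a fraction in (0, 1).
#' @param ef_low,ef_high Bounds of the EF uncertainty range.
#' @return `ipcc_tier1()`: numeric vector of emissions. `ipcc_range()`: a
#'   tibble with columns `dose`, `low`, `point`, `high`.
#' @examples
#' ipcc_tier1(300, ef = 0.03)  # 9 kg N2O-N: the Tier 1 upper bound at 300 kg N
#' ipcc_range(c(0, 100, 300))
#' @export
ipcc_tier1 <- function(dose, ef = 0.01) {
  if (any(dose < 0)) stop("dose must be nonnegative", call. = FALSE)
  if (ef <= 0 || ef >= 1) stop("ef must lie in (0, 1)", call. = FALSE)
  ef * dose
}

#' @rdname ipcc_tier1
#' @export
ipcc_range <- function(dose, ef = 0.01, ef_low = 0.003, ef_high = 0.03) {
  tibble::tibble(
    dose = dose,
    low = ipcc_tier1(dose, ef_low),
    point = ipcc_tier1(dose, ef),
    high = ipcc_tier1(dose, ef_high)
  )
}
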