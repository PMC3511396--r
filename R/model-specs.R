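#' Model structures relating N2O emission to applied N
#'
#' Thirteen model structures are supported, named by a three-part code:
#' response function (`NL` exponential, `L` linear), use of the applied-N
#' dose as explanatory variable (`N` yes, `0` no), and the fixed/random
#' status of the intercept and of the applied-N effect (`F`/`R` for each).
#' A trailing `-B` marks the two Bayesian variants, which share the
#' two-random-effect structure of `NL-N-RR` and `L-N-RR` but are estimated
#' by MCMC ([run_mcmc()]) rather than maximum likelihood ([fit_ml()]).
#'
#' The mean response is `mu0 + mu1 * X` for linear models and
#' `exp(mu0 + mu1 * X)` for exponential models, with publication-specific
#' deviations `a0` on the intercept and `a1` on the N effect when the
#' corresponding component is random.
#'
#' @param name Model name, one of `model_names()`.
#' @return `model_spec()` returns an object of class `"model_spec"`: a list
#'   with fields `name`, `linear`, `uses_N`, `random_intercept`,
#'   `random_slope`, `bayesian`. `model_specs()` returns a tibble with one
#'   row per model. `model_names()` returns the character vector of the
#'   thirteen names.
#' @examples
#' model_spec("NL-N-RR")
#' model_specs()
#' @export
model_spec <- function(name) {
  tab <- model_specs()
  row <- tab[tab$name == name, ]
  if (nrow(row) != 1L) {
    stop("unknown model name '", name, "'; see model_names()", call. = FALSE)
  }
  structure(as.list(row), class = "model_spec")
}

#' @rdname model_spec
#' @export
model_specs <- function() {
  tibble::tribble(
    ~name,        ~linear, ~uses_N, ~random_intercept, ~random_slope, ~bayesian,
    "NL-N-FF",    FALSE,   TRUE,    FALSE,             FALSE,         FALSE,
    "NL-0-R",     FALSE,   FALSE,   TRUE,              FALSE,         FALSE,
    "NL-N-RF",    FALSE,   TRUE,    TRUE,              FALSE,         FALSE,
    "NL-N-FR",    FALSE,   TRUE,    FALSE,             TRUE,          FALSE,
    "NL-N-RR",    FALSE,   TRUE,    TRUE,              TRUE,          FALSE,
    "NL-N-RR-B",  FALSE,   TRUE,    TRUE,              TRUE,          TRUE,
    "L-0-F",      TRUE,    FALSE,   FALSE,             FALSE,         FALSE,
    "L-N-FF",     TRUE,    TRUE,    FALSE,             FALSE,         FALSE,
    "L-0-R",      TRUE,    FALSE,   TRUE,              FALSE,         FALSE,
    "L-N-RF",     TRUE,    TRUE,    TRUE,              FALSE,         FALSE,
    "L-N-FR",     TRUE,    TRUE,    FALSE,             TRUE,          FALSE,
    "L-N-RR",     TRUE,    TRUE,    TRUE,              TRUE,          FALSE,
    "L-N-RR-B",   TRUE,    TRUE,    TRUE,              TRUE,          TRUE
  )
}

#' @rdname model_spec
#' @export
model_names <- function() model_specs()$name

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$name, "\n", sep = "")
  cat("  response:        ", if (x$linear) "linear" else "exponential", "\n", sep = "")
  cat("  uses applied N:  ", x$uses_N, "\n", sep = "")
  cat("  random intercept:", x$random_intercept, "\n")
  cat("  random N effect: ", x$random_slope, "\n")
  cat("  estimation:      ", if (x$bayesian) "Bayesian (MCMC)" else "maximum likelihood", "\n", sep = "")
  invisible(x)
}

as_model_spec <- function(spec) {
  if (inherits(spec, "model_spec")) return(spec)
  if (is.character(spec) && length(spec) == 1L) return(model_spec(spec))
  stop("`spec` must be a model name or a model_spec object", call. = FALSE)
}

#' Parameter set for an emission model
#'
#' Bundles the five population-level parameters shared by all model
#' structures: `mu0` the mean background term (intercept), `mu1` the mean
#' applied-N effect per kg N ha^-1, `sigma0` and `sigma1` the
#' between-publication standard deviations of the intercept and the N
#' effect, and `tau` the residual standard deviation
#' (kg N2O-N ha^-1 yr^-1). For exponential models `mu0` and `mu1` act on
#' the log scale.
#'
#' @param mu0,mu1 Fixed-effect means. `mu1` may be `NA` for models without
#'   the applied-N term.
#' @param sigma0,sigma1 Between-publication SDs; must be 0 for components a
#'   given model treats as fixed.
#' @param tau Residual SD, `>= 0`.
#' @return An object of class `"param_set"` (named list).
#' @examples
#' param_set(mu0 = 0.19, mu1 = 0.0037, sigma0 = 0.72, sigma1 = 0.0025, tau = 1.94)
#' @export
param_set <- function(mu0, mu1 = NA_real_, sigma0 = 0, sigma1 = 0, tau = 0) {
  stopifnot(is.numeric(mu0), length(mu0) == 1L)
  if (any(c(sigma0, sigma1, tau) < 0, na.rm = TRUE)) {
    stop("sigma0, sigma1 and tau must be nonnegative", call. = FALSE)
  }
  structure(
    list(mu0 = as.numeric(mu0), mu1 = as.numeric(mu1),
         sigma0 = as.numeric(sigma0), sigma1 = as.numeric(sigma1),
         tau = as.numeric(tau)),
    class = "param_set"
  )
}

#' @export
print.param_set <- function(x, ...) {
  cat("<param_set> mu0 =", x$mu0, " mu1 =", x$mu1,
      " sigma0 =", x$sigma0, " sigma1 =", x$sigma1, " tau =", x$tau, "\n")
  invisible(x)
}

# check a param_set against a model structure; sigma for a fixed component
# must be zero (strict = TRUE errors, otherwise returns FALSE)
validate_params <- function(spec, params, strict = TRUE) {
  spec <- as_model_spec(spec)
  bad <- character(0)
  if (!spec$random_intercept && isTRUE(params$sigma0 > 0)) bad <- c(bad, "sigma0")
  if (!spec$random_slope && isTRUE(params$sigma1 > 0)) bad <- c(bad, "sigma1")
  if (spec$uses_N && (is.null(params$mu1) || is.na(params$mu1))) bad <- c(bad, "mu1 (missing)")
  if (length(bad) && strict) {
    stop("parameters inconsistent with model ", spec$name, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  length(bad) == 0L
}

#' Published reference parameter estimates
#'
#' Parameter estimates for the thirteen models as reported by a global
#' meta-analysis of 985 field measurements of annual N2O emission from 203
#' publications (the Stehfest & Bouwman compilation restricted to fertilized
#' agricultural mineral soils). These values are useful as realistic
#' generating truths for simulation studies and as worked-example inputs;
#' they are not a substitute for fitting your own data.
#'
#' Standard errors are available for `mu0` and `mu1` only, as published.
#'
#' @param name Optional model name; if given, returns that row as a
#'   [param_set()] (standard errors attached as attribute `"se"`).
#' @return A tibble with columns `name`, `mu0`, `se_mu0`, `mu1`, `se_mu1`,
#'   `sigma0`, `sigma1`, `tau`, or a `param_set` if `name` is supplied.
#' @examples
#' ref_params()
#' ref_params("NL-N-RR")
#' @export
ref_params <- function(name = NULL) {
  tab <- tibble::tribble(
    ~name,       ~mu0,   ~se_mu0, ~sigma0, ~mu1,      ~se_mu1, ~sigma1, ~tau,
    "NL-N-FF",    0.25,   0.096,  0,       0.0042,    0.0003,  0,       3.96,
    "NL-0-R",     0.87,   0.077,  0.84,    NA_real_,  NA_real_, 0,      2.84,
    "NL-N-RF",   -0.068,  0.092,  0.83,    0.0050,    0.0003,  0,       2.09,
    "NL-N-FR",    0.31,   0.068,  0,       0.0033,    0.0005,  0.0043,  2.13,
    "NL-N-RR",    0.19,   0.09,   0.72,    0.0037,    0.0004,  0.0025,  1.94,
    "NL-N-RR-B", -0.21,   0.13,   0.92,    0.0038,    0.0005,  0.0032,  1.91,
    "L-0-F",      2.40,   0.14,   0,       NA_real_,  NA_real_, 0,      4.26,
    "L-N-FF",     0.69,   0.19,   0,       0.0138,    0.0011,  0,       3.96,
    "L-0-R",      2.78,   0.27,   3.44,    NA_real_,  NA_real_, 0,      2.91,
    "L-N-RF",     0.99,   0.28,   3.16,    0.0130,    0.0010,  0,       2.67,
    "L-N-FR",     1.09,   0.11,   0,       0.0113,    0.0017,  0.0195,  2.12,
    "L-N-RR",     1.04,   0.13,   0.70,    0.0117,    0.0017,  0.0187,  2.08,
    "L-N-RR-B",   1.04,   0.14,   0.76,    0.0117,    0.0017,  0.0189,  2.08
  )
  if (is.null(name)) return(tab)
  row <- tab[tab$name == name, ]
  if (nrow(row) != 1L) stop("unknown model name '", name, "'", call. = FALSE)
  out <- param_set(mu0 = row$mu0, mu1 = row$mu1, sigma0 = row$sigma0,
                   sigma1 = row$sigma1, tau = row$tau)
  attr(out, "se") <- c(mu0 = row$se_mu0, mu1 = row$se_mu1)
  out
}

#' Published model-comparison statistics
#'
#' AIC, BIC (eleven likelihood-based models) and DIC (two Bayesian models)
#' as reported for the same global dataset as [ref_params()]. Useful for
#' exercising [model_selection_table()] and [select_ensemble()] logic
#' without refitting the original data.
#'
#' @return A tibble with columns `name`, `aic`, `bic`, `dic` (`NA` where a
#'   criterion does not apply).
#' @export
ref_fit_stats <- function() {
  tibble::tribble(
    ~name,       ~aic,    ~bic,    ~dic,
    "NL-N-FF",   5513.1,  5527.8,  NA_real_,
    "NL-0-R",    5091.9,  5106.5,  NA_real_,
    "NL-N-RF",   4553.9,  4573.5,  NA_real_,
    "NL-N-FR",   4598.9,  4618.5,  NA_real_,
    "NL-N-RR",   4482.7,  4507.1,  NA_real_,
    "NL-N-RR-B", NA_real_, NA_real_, 4196.71,
    "L-0-F",     5653.9,  5663.7,  NA_real_,
    "L-N-FF",    5512.1,  5526.8,  NA_real_,
    "L-0-R",     5268.5,  5283.2,  NA_real_,
    "L-N-RF",    5117.4,  5136.9,  NA_real_,
    "L-N-FR",    4698.0,  4717.5,  NA_real_,
    "L-N-RR",    4693.2,  4717.6,  NA_real_,
    "L-N-RR-B",  NA_real_, NA_real_, 4421.63
  )
}
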