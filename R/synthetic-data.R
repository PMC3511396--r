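#' Design for a synthetic emission dataset
#'
#' Describes the hierarchical layout of a simulated compilation of field
#' experiments: how many publications, how many N doses per publication,
#' how many replicates per dose, and how doses are sampled. Doses are drawn
#' as a mixture: each publication contributes a structural control at dose
#' 0 (when `ensure_control` is `TRUE`), and remaining doses are 0 with
#' probability `zero_fraction` or otherwise drawn from a lognormal
#' distribution truncated at `max_dose` by inverse-CDF sampling.
#'
#' @param n_publications Number of synthetic publications (groups).
#' @param doses_per_publication Doses measured within each publication.
#' @param replicates_per_dose Replicate measurements per dose.
#' @param ensure_control First dose of every publication fixed at 0.
#' @param zero_fraction Probability that a *sampled* (non-structural) dose
#'   is 0, reflecting additional unfertilized plots.
#' @param dose_meanlog,dose_sdlog Lognormal parameters of positive doses.
#' @param max_dose Truncation point, kg N ha^-1.
#' @return An object of class `"design_config"` (named list).
#' @seealso [default_world_design()], [simulate_emissions()]
#' @export
design_config <- function(n_publications,
                          doses_per_publication = 3,
                          replicates_per_dose = 1,
                          ensure_control = TRUE,
                          zero_fraction = 0.05,
                          dose_meanlog = 5.17,
                          dose_sdlog = 0.7,
                          max_dose = 500) {
  stopifnot(n_publications >= 1, doses_per_publication >= 1,
            replicates_per_dose >= 1, zero_fraction >= 0, zero_fraction <= 1,
            max_dose > 0)
  structure(
    list(n_publications = as.integer(n_publications),
         doses_per_publication = as.integer(doses_per_publication),
         replicates_per_dose = as.integer(replicates_per_dose),
         ensure_control = isTRUE(ensure_control),
         zero_fraction = zero_fraction,
         dose_meanlog = dose_meanlog, dose_sdlog = dose_sdlog,
         max_dose = max_dose),
    class = "design_config"
  )
}

#' World-scale default design
#'
#' A design of 203 publications with 3 doses each (a control at 0 plus
#' sampled doses), calibrated so the marginal dose distribution matches the
#' world-scale summaries of the reference compilation: median near 100,
#' mean near 124, maximum 500 kg N ha^-1, with a point mass at dose 0.
#'
#' @return A [design_config()].
#' @export
default_world_design <- function() {
  design_config(n_publications = 203)
}

# draw all doses for a design; returns matrix-free vector ordered by
# publication then dose index
draw_doses <- function(design) {
  n_total <- design$n_publications * design$doses_per_publication
  structural <- rep(FALSE, n_total)
  if (design$ensure_control) {
    structural[seq(1, n_total, by = design$doses_per_publication)] <- TRUE
  }
  n_sampled <- sum(!structural)
  zero <- stats::runif(n_sampled) < design$zero_fraction
  # inverse-CDF truncation keeps the draw count deterministic
  fmax <- stats::plnorm(design$max_dose, design$dose_meanlog, design$dose_sdlog)
  u <- stats::runif(n_sampled) * fmax
  pos <- stats::qlnorm(u, design$dose_meanlog, design$dose_sdlog)
  sampled <- ifelse(zero, 0, pos)
  doses <- numeric(n_total)
  doses[!structural] <- sampled
  doses
}

#' Simulate a hierarchical emission dataset
#'
#' Generates data from the exact stochastic structure the models assume:
#' publication effects `a0_i ~ N(0, sigma0^2)` and `a1_i ~ N(0, sigma1^2)`
#' (only those the model declares random), and
#' `Y_ijk = mean_response(dose_ij, a0_i, a1_i) + eps_ijk` with
#' `eps_ijk ~ N(0, tau^2)`. Negative simulated emissions are kept: the
#' models' Gaussian residual assumption implies them, and truncating would
#' change the likelihood being tested.
#'
#' The generating truth (spec, parameters, and the realized per-publication
#' effects, exactly as drawn) is attached as attribute `"truth"`;
#' retrieve it with [sim_truth()].
#'
#' @param spec Model name or [model_spec()] (non-Bayesian structure; the
#'   Bayesian variants share the generating process of their ML
#'   counterparts).
#' @param params A [param_set()] consistent with `spec` (a nonzero sigma
#'   for a fixed component is an error).
#' @param design A [design_config()].
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @return Emission tibble in the canonical columns of
#'   [read_emission_table()], with metadata columns set to values that pass
#'   [apply_exclusion_filters()].
#' @examples
#' d <- simulate_emissions("NL-N-RR", ref_params("NL-N-RR"),
#'                         design_config(10), seed = 1)
#' sim_truth(d)$params
#' @export
simulate_emissions <- function(spec, params, design, seed = NULL) {
  spec <- as_model_spec(spec)
  validate_params(spec, params)
  if (!is.null(seed)) set.seed(seed)

  G <- design$n_publications
  a0 <- if (spec$random_intercept) stats::rnorm(G, 0, params$sigma0) else rep(0, G)
  a1 <- if (spec$random_slope) stats::rnorm(G, 0, params$sigma1) else rep(0, G)

  doses <- draw_doses(design)
  pub_of_dose <- rep(seq_len(G), each = design$doses_per_publication)
  K <- design$replicates_per_dose
  idx <- rep(seq_along(doses), each = K)
  pub <- pub_of_dose[idx]
  dose <- doses[idx]
  replicate <- rep(seq_len(K), times = length(doses))

  mu <- mean_response(spec, params, dose,
                      a0 = if (spec$random_intercept) a0[pub] else 0,
                      a1 = if (spec$random_slope) a1[pub] else 0)
  y <- mu + stats::rnorm(length(mu), 0, params$tau)

  ids <- sprintf("pub%03d", seq_len(G))
  out <- tibble::tibble(
    publication_id = ids[pub],
    n_rate_kg_ha = dose,
    n2o_kg_n_ha_yr = y,
    replicate = as.integer(replicate),
    land_use = "agricultural",
    soil_class = "mineral",
    gas_measured = "N2O",
    inhibitor = FALSE,
    grazing = FALSE
  )
  attr(out, "truth") <- list(
    spec = spec, params = params, design = design, seed = seed,
    effects = tibble::tibble(publication_id = ids, a0 = a0, a1 = a1)
  )
  out
}

#' @rdname simulate_emissions
#' @param data A tibble returned by `simulate_emissions()`.
#' @export
sim_truth <- function(data) {
  t <- attr(data, "truth")
  if (is.null(t)) stop("no generating truth attached to this dataset", call. = FALSE)
  t
}
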