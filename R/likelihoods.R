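# Marginal likelihoods for the emission models.
#
# Linear structures admit an exact closed form: within a publication the
# observations are jointly Gaussian with covariance
#   V = tau^2 I + sigma0^2 J + sigma1^2 x x'
# (terms per model structure). Exponential structures have no closed form;
# publication random effects are integrated out by adaptive Gauss-Hermite
# quadrature recentered at each publication's conditional mode, with
# n_nodes = 1 giving the Laplace approximation. Everything is vectorized
# across publications: mode finding runs one damped Newton iteration for
# all publications simultaneously, and each quadrature node costs one pass
# over the full observation vector.

# decompose data into parallel vectors; groups ordered by first appearance
data_index <- function(data) {
  g <- match(data$publication_id, unique(data$publication_id))
  list(
    g = g,
    G = max(g),
    ids = unique(data$publication_id),
    x = as.numeric(data$n_rate_kg_ha),
    y = as.numeric(data$n2o_kg_n_ha_yr),
    n = nrow(data)
  )
}

group_sum <- function(v, g, G) {
  out <- numeric(G)
  s <- rowsum(v, g)
  out[as.integer(rownames(s))] <- s
  out
}

logsumexp <- function(m) {
  # rowwise log-sum-exp of a matrix
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Exact marginal log-likelihood of a linear mixed emission model
#'
#' Per publication, the response vector is multivariate normal with mean
#' `mu0 + mu1 * x` (applied-N term only for models that use it) and
#' covariance `sigma0^2 J + sigma1^2 x x' + tau^2 I` with terms per the
#' model structure; the log-density is evaluated by Cholesky factorization
#' and summed over publications.
#'
#' @param spec Linear model name or [model_spec()].
#' @param params A [param_set()].
#' @param data Emission tibble with `publication_id`, `n_rate_kg_ha`,
#'   `n2o_kg_n_ha_yr`.
#' @return The marginal log-likelihood (scalar).
#' @export
loglik_linear_mixed <- function(spec, params, data) {
  spec <- as_model_spec(spec)
  if (!spec$linear) stop("spec must be a linear model", call. = FALSE)
  validate_params(spec, params)
  d <- data_index(data)
  tau2 <- params$tau^2
  if (tau2 <= 0) stop("singular covariance: tau must be positive", call. = FALSE)
  mu <- params$mu0 + if (spec$uses_N) params$mu1 * d$x else 0
  r <- d$y - mu
  ri <- spec$random_intercept && params$sigma0 > 0
  rs <- spec$random_slope && params$sigma1 > 0
  one <- rep(1, d$n)
  ni <- group_sum(one, d$g, d$G)
  sr2 <- group_sum(r^2, d$g, d$G)
  # Woodbury / determinant-lemma form of the per-publication Gaussian
  # density, vectorized across publications via group sums
  if (ri && rs) {
    s02 <- params$sigma0^2
    s12 <- params$sigma1^2
    sx <- group_sum(d$x, d$g, d$G)
    sx2 <- group_sum(d$x^2, d$g, d$G)
    sr <- group_sum(r, d$g, d$G)
    srx <- group_sum(r * d$x, d$g, d$G)
    m11 <- tau2 / s02 + ni
    m22 <- tau2 / s12 + sx2
    detm <- m11 * m22 - sx^2
    logdet <- ni * log(tau2) + log(s02 * s12 * detm / tau2^2)
    quad <- (sr2 - (m22 * sr^2 - 2 * sx * sr * srx + m11 * srx^2) / detm) / tau2
  } else if (ri || rs) {
    s2 <- if (ri) params$sigma0^2 else params$sigma1^2
    z <- if (ri) one else d$x
    szz <- group_sum(z^2, d$g, d$G)
    srz <- group_sum(r * z, d$g, d$G)
    logdet <- ni * log(tau2) + log1p(s2 * szz / tau2)
    quad <- (sr2 - s2 * srz^2 / (tau2 + s2 * szz)) / tau2
  } else {
    logdet <- ni * log(tau2)
    quad <- sr2 / tau2
  }
  -0.5 * sum(ni * log(2 * pi) + logdet + quad)
}

# joint log-density h_i(v) of (data_i, v) given parameters, for all
# publications at once, in STANDARDIZED latent coordinates v = u / sigma
# (prior N(0,1)), which keeps Newton steps well-scaled even when the two
# random components live on very different scales. v0, v1 are G-vectors
# (ignored when the component is fixed). The linear predictor is clamped
# at +-300 as an overflow guard; it never binds near a mode.
latent_joint <- function(d, spec, params, v0, v1, link, derivs = FALSE) {
  eta <- params$mu0 + if (spec$uses_N) params$mu1 * d$x else 0
  if (spec$random_intercept) eta <- eta + params$sigma0 * v0[d$g]
  if (spec$random_slope) eta <- eta + params$sigma1 * v1[d$g] * d$x
  eta <- pmin(pmax(eta, -300), 300)
  m <- if (link == "log") exp(eta) else eta
  tau2 <- params$tau^2
  llobs <- -0.5 * log(2 * pi * tau2) - (d$y - m)^2 / (2 * tau2)
  h <- group_sum(llobs, d$g, d$G)
  if (spec$random_intercept) h <- h + stats::dnorm(v0, log = TRUE)
  if (spec$random_slope) h <- h + stats::dnorm(v1, log = TRUE)
  if (!derivs) return(list(h = h))
  mp <- if (link == "log") m else 1            # dm/deta
  w1 <- (d$y - m) * mp / tau2                  # d llobs / deta
  w2 <- if (link == "log") m * (d$y - 2 * m) / tau2 else rep(-1 / tau2, d$n)
  out <- list(h = h)
  if (spec$random_intercept) {
    out$g0 <- params$sigma0 * group_sum(w1, d$g, d$G) - v0
    out$h00 <- params$sigma0^2 * group_sum(w2, d$g, d$G) - 1
  }
  if (spec$random_slope) {
    out$g1 <- params$sigma1 * group_sum(w1 * d$x, d$g, d$G) - v1
    out$h11 <- params$sigma1^2 * group_sum(w2 * d$x^2, d$g, d$G) - 1
  }
  if (spec$random_intercept && spec$random_slope) {
    out$h01 <- params$sigma0 * params$sigma1 * group_sum(w2 * d$x, d$g, d$G)
  }
  out
}

# damped Newton ascent to the conditional mode of the standardized latent
# effects, vectorized over publications. Away from the mode the
# exponential-mean joint density need not be concave, so the Hessian is
# ridged (Gershgorin bound) wherever it is not negative definite, and
# steps are capped and halved until they ascend.
find_modes <- function(d, spec, params, link, tol = 1e-8, max_iter = 200) {
  ri <- spec$random_intercept
  rs <- spec$random_slope
  v0 <- numeric(d$G)
  v1 <- numeric(d$G)
  cur <- latent_joint(d, spec, params, v0, v1, link, derivs = TRUE)
  gmax <- Inf
  for (iter in seq_len(max_iter)) {
    if (ri && rs) {
      lam_max <- ((cur$h00 + cur$h11) +
                    sqrt((cur$h00 - cur$h11)^2 + 4 * cur$h01^2)) / 2
      ridge <- pmax(0, lam_max + 1e-3)
      h00 <- cur$h00 - ridge
      h11 <- cur$h11 - ridge
      det <- h00 * h11 - cur$h01^2
      s0 <- -( h11 * cur$g0 - cur$h01 * cur$g1) / det
      s1 <- -(-cur$h01 * cur$g0 + h00 * cur$g1) / det
      gmax <- pmax(abs(cur$g0), abs(cur$g1))
    } else if (ri) {
      s0 <- -cur$g0 / pmin(cur$h00, -1e-3)
      s1 <- numeric(d$G)
      gmax <- abs(cur$g0)
    } else {
      s0 <- numeric(d$G)
      s1 <- -cur$g1 / pmin(cur$h11, -1e-3)
      gmax <- abs(cur$g1)
    }
    if (max(gmax) < tol) break
    # trust cap: no publication moves more than 4 prior SDs per iteration
    len <- sqrt(s0^2 + s1^2)
    shrink <- pmin(1, 4 / pmax(len, 1e-300))
    s0 <- s0 * shrink
    s1 <- s1 * shrink
    step <- rep(1, d$G)
    repeat {
      cand <- latent_joint(d, spec, params, v0 + step * s0, v1 + step * s1,
                           link, derivs = FALSE)
      worse <- cand$h < cur$h - 1e-12
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
      if (min(step) < 1e-12) {
        step[worse] <- 0
        break
      }
    }
    v0 <- v0 + step * s0
    v1 <- v1 + step * s1
    cur <- latent_joint(d, spec, params, v0, v1, link, derivs = TRUE)
  }
  # per-publication quasi-Newton fallback for the rare stalled cases
  stalled <- which(gmax >= 1e-6)
  for (i in stalled) {
    sub <- list(g = rep(1L, sum(d$g == i)), G = 1L, ids = d$ids[i],
                x = d$x[d$g == i], y = d$y[d$g == i], n = sum(d$g == i))
    negh <- function(v) {
      -latent_joint(sub, spec, params, v[1], v[2], link)$h
    }
    o <- tryCatch(
      stats::optim(c(v0[i], v1[i]), negh, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL
    )
    if (is.null(o)) {
      stop("conditional mode search failed for publication '", d$ids[i],
           "'", call. = FALSE)
    }
    v0[i] <- o$par[1]
    v1[i] <- o$par[2]
  }
  if (length(stalled)) {
    cur <- latent_joint(d, spec, params, v0, v1, link, derivs = TRUE)
    gm <- if (ri && rs) pmax(abs(cur$g0), abs(cur$g1)) else
      if (ri) abs(cur$g0) else abs(cur$g1)
    if (max(gm) >= 1e-4) {
      stop("conditional mode search failed for publication '",
           d$ids[which.max(gm)], "'", call. = FALSE)
    }
  }
  list(v0 = v0, v1 = v1, at = cur)
}

gh_nodes <- function(n_nodes) {
  if (n_nodes == 1L) return(list(x = 0, w = sqrt(pi)))
  pracma::gaussHermite(n_nodes)
}

#' Adaptive Gauss-Hermite marginal log-likelihood
#'
#' Marginal log-likelihood of a mixed emission model with the publication
#' random effects integrated out numerically: one-dimensional quadrature
#' for a single random component, a tensor grid for two. The grid is
#' recentered at each publication's conditional mode and scaled by the
#' local curvature (adaptive quadrature); `n_nodes = 1` gives the Laplace
#' approximation. Models without random components reduce to the exact
#' Gaussian residual log-likelihood.
#'
#' Intended for the exponential models; with `link = "identity"` the same
#' machinery evaluates a linear structure, which is useful as a
#' cross-check against [loglik_linear_mixed()] (the integrand is then
#' Gaussian, so any node count is exact).
#'
#' @inheritParams loglik_linear_mixed
#' @param spec Exponential model name or [model_spec()] (a linear spec is
#'   only accepted together with `link = "identity"`).
#' @param n_nodes Odd number of quadrature nodes per dimension (default 9).
#' @param link `"log"` (exponential mean, the default) or `"identity"`.
#' @return The marginal log-likelihood (scalar).
#' @export
loglik_nonlinear_mixed <- function(spec, params, data, n_nodes = 9,
                                   link = c("log", "identity")) {
  spec <- as_model_spec(spec)
  link <- match.arg(link)
  if (spec$linear && link == "log") {
    stop("spec is linear; use loglik_linear_mixed() or link = 'identity'",
         call. = FALSE)
  }
  if (!spec$linear && link == "identity") {
    stop("identity link is only for cross-checking linear structures",
         call. = FALSE)
  }
  if (n_nodes < 1 || n_nodes %% 2 == 0) {
    stop("n_nodes must be odd and >= 1", call. = FALSE)
  }
  validate_params(spec, params)
  d <- data_index(data)
  ri <- spec$random_intercept && params$sigma0 > 0
  rs <- spec$random_slope && params$sigma1 > 0
  # treat zero-variance components as fixed: the integral degenerates
  eff_spec <- spec
  eff_spec$random_intercept <- ri
  eff_spec$random_slope <- rs

  if (!ri && !rs) {
    return(sum(latent_joint(d, eff_spec, params, numeric(d$G), numeric(d$G),
                            link)$h))
  }

  modes <- find_modes(d, eff_spec, params, link)
  gh <- gh_nodes(n_nodes)

  if (ri && rs) {
    q00 <- -modes$at$h00; q01 <- -modes$at$h01; q11 <- -modes$at$h11
    det <- pmax(q00 * q11 - q01^2, .Machine$double.eps)
    s00 <- q11 / det; s01 <- -q01 / det; s11 <- q00 / det
    l11 <- sqrt(pmax(s00, .Machine$double.eps))
    l21 <- s01 / l11
    l22 <- sqrt(pmax(s11 - l21^2, .Machine$double.eps))
    grid <- expand.grid(k1 = seq_len(n_nodes), k2 = seq_len(n_nodes))
    K <- nrow(grid)
    hmat <- matrix(0, d$G, K)
    lw <- numeric(K)
    for (k in seq_len(K)) {
      z1 <- gh$x[grid$k1[k]]; z2 <- gh$x[grid$k2[k]]
      v0 <- modes$v0 + sqrt(2) * l11 * z1
      v1 <- modes$v1 + sqrt(2) * (l21 * z1 + l22 * z2)
      hmat[, k] <- latent_joint(d, eff_spec, params, v0, v1, link)$h
      lw[k] <- log(gh$w[grid$k1[k]]) + log(gh$w[grid$k2[k]]) + z1^2 + z2^2
    }
    per_pub <- log(2) + log(l11 * l22) +
      logsumexp(sweep(hmat, 2, lw, "+"))
  } else {
    q <- if (ri) -modes$at$h00 else -modes$at$h11
    a <- 1 / sqrt(pmax(q, .Machine$double.eps))
    hmat <- matrix(0, d$G, n_nodes)
    lw <- numeric(n_nodes)
    for (k in seq_len(n_nodes)) {
      z <- gh$x[k]
      shift <- sqrt(2) * a * z
      v0 <- if (ri) modes$v0 + shift else numeric(d$G)
      v1 <- if (rs) modes$v1 + shift else numeric(d$G)
      hmat[, k] <- latent_joint(d, eff_spec, params, v0, v1, link)$h
      lw[k] <- log(gh$w[k]) + z^2
    }
    per_pub <- 0.5 * log(2) + log(a) + logsumexp(sweep(hmat, 2, lw, "+"))
  }
  sum(per_pub)
}
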