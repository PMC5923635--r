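#' MCMC run configuration
#'
#' Defaults mirror the study protocol for this class of model: two parallel
#' chains, 20,000 burn-in iterations, thinning of 100, and 20,000 retained
#' draws per chain.  Tests and desk-scale experiments use reduced settings.
#'
#' @param chains Number of chains (>= 1; convergence diagnostics need 2).
#' @param iterations Total iterations per chain, including burn-in.
#' @param burn_in Iterations discarded; proposal scales adapt only here.
#' @param thinning Keep every `thinning`-th post-burn-in draw.
#' @param seed Integer seed; per-chain streams are derived from it.
#' @param adapt_window Iterations between Robbins-Monro scale updates.
#' @param target_acceptance Target acceptance rate for adapted blocks.
#' @param delta_substeps Repetitions per sweep of the hyperparameter
#'   block: the conjugate precision draws and the joint scale/transfer
#'   kernels, including the scaling-parameter moves.  The scaling
#'   parameter and the variance components are the slowest-mixing
#'   quantities in this posterior and these kernels are far cheaper than
#'   the field sweeps, so repeating them raises effective sample size per
#'   iteration at small cost.
#' @param field_sweeps Scans of the latent-field/intercept block per
#'   iteration.  More scans make each iteration a more thorough sweep,
#'   reducing autocorrelation per retained draw at proportional cost.
#' @param scales Named initial proposal standard deviations per block
#'   (`theta`, `s1`, `s2`, `u1`, `u2`, `alpha1`, `alpha2`, `log_delta`).
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 2, iterations = 2020000, burn_in = 20000,
                        thinning = 100, seed = 1, adapt_window = 50,
                        target_acceptance = 0.44, delta_substeps = 8,
                        field_sweeps = 1, scales = NULL) {
  stopifnot(chains >= 1, thinning >= 1, burn_in >= 0, burn_in < iterations)
  if ((iterations - burn_in) %% thinning != 0) {
    stop("(iterations - burn_in) must be divisible by thinning")
  }
  sc <- c(theta = 0.3, s1 = 0.3, s2 = 0.3, u1 = 0.3, u2 = 0.3,
          alpha1 = 0.05, alpha2 = 0.05, log_delta = 0.2,
          shared_scale = 0.3, theta_scale = 0.3, s1_scale = 0.3,
          s2_scale = 0.3, u1_scale = 0.3, u2_scale = 0.3,
          shared_transfer = 0.1, transfer_s1 = 0.1, transfer_s2 = 0.1,
          mix_s1 = 0.1, mix_s2 = 0.1)
  if (!is.null(scales)) {
    stopifnot(all(names(scales) %in% names(sc)), all(scales > 0))
    sc[names(scales)] <- scales
  }
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning),
                 seed = as.integer(seed),
                 adapt_window = as.integer(adapt_window),
                 target_acceptance = target_acceptance,
                 delta_substeps = as.integer(delta_substeps),
                 field_sweeps = as.integer(field_sweeps),
                 scales = sc),
            class = "mcmc_config")
}

#' Conjugate Gibbs draw for a precision parameter
#'
#' For an ICAR field (pass the graph) the full conditional is
#' `Gamma(a + (n - c)/2, b + sum of squared neighbour differences / 2)`
#' with `c` the number of connected components; for an unstructured field
#' (graph `NULL`) it is `Gamma(a + n/2, b + sum(x^2)/2)`.  Shape/rate
#' parameterization throughout.
#'
#' @param x The current field.
#' @param hyper Length-2 `c(shape, rate)` Gamma hyperprior.
#' @param graph An [areal_graph], or `NULL` for an unstructured field.
#' @return A single precision draw (uses the R RNG stream).
#' @export
gibbs_update_precision <- function(x, hyper, graph = NULL) {
  stopifnot(length(hyper) == 2, all(hyper > 0))
  if (is.null(graph)) {
    shape <- hyper[1] + length(x) / 2
    rate <- hyper[2] + sum(x^2) / 2
  } else {
    stopifnot(length(x) == graph$n)
    e <- graph$edges
    quad <- if (nrow(e)) sum((x[e[, 1]] - x[e[, 2]])^2) else 0
    shape <- hyper[1] + (graph$n - graph$n_components) / 2
    rate <- hyper[2] + quad / 2
  }
  stats::rgamma(1, shape = shape, rate = rate)
}

#' Recenter the spatial fields of a state
#'
#' Subtracts the mean from the shared and both specific surfaces and
#' absorbs the means into the intercepts
#' (`alpha1 <- alpha1 + delta*mean(theta) + mean(s1)`;
#' `alpha2 <- alpha2 + mean(theta)/delta + mean(s2)`), so the relative
#' risks are unchanged.  This projects along the flat directions of the
#' improper ICAR priors, keeping the field levels identified against the
#' intercepts.
#'
#' @param state A [model_state].
#' @return The recentered [model_state].
#' @export
recenter <- function(state) {
  delta <- exp(state$log_delta)
  mt <- mean(state$theta); m1 <- mean(state$s1); m2 <- mean(state$s2)
  state$theta <- state$theta - mt
  state$s1 <- state$s1 - m1
  state$s2 <- state$s2 - m2
  state$alpha[1] <- state$alpha[1] + delta * mt + m1
  state$alpha[2] <- state$alpha[2] + mt / delta + m2
  state
}

# Canonical block order shared with the compiled iteration kernel.
.block_order <- c("theta", "s1", "s2", "u1", "u2", "alpha1", "alpha2",
                  "log_delta", "shared_scale", "theta_scale",
                  "shared_transfer", "transfer_s1", "transfer_s2",
                  "mix_s1", "mix_s2", "s1_scale", "s2_scale",
                  "u1_scale", "u2_scale")

.block_idx <- function(blocks) match(blocks, .block_order)

# ---- internal sampler workspace -------------------------------------------
# Mutable environment holding the data, graph structures and current state,
# with Poisson means maintained incrementally across single-site updates.

.make_workspace <- function(state, table, expected, graph,
                            use_likelihood = TRUE, shared = TRUE) {
  if (!identical(as.character(table$area_id), graph$area_ids)) {
    bad <- which(as.character(table$area_id) != graph$area_ids)[1]
    stop("counts/graph area mismatch at position ", bad, ": table has '",
         table$area_id[bad], "', graph has '", graph$area_ids[bad], "'")
  }
  ws <- new.env(parent = emptyenv())
  ws$O1 <- table$O1; ws$O2 <- table$O2
  ws$e1 <- expected$e[, 1]; ws$e2 <- expected$e[, 2]
  ws$n <- graph$n
  ws$m <- graph$m
  ws$W <- adjacency_matrix(graph)
  ws$graph <- graph
  ws$island <- graph$m == 0L
  cls <- .graph_colour_classes(graph)
  ws$colours <- lapply(cls, function(ix) as.integer(ix[!ws$island[ix]]))
  ws$colours <- ws$colours[lengths(ws$colours) > 0]
  nb <- .neighbour_list(graph)
  ws$nbr_ptr <- c(0L, cumsum(lengths(nb)))
  ws$nbr_idx <- as.integer(unlist(nb) - 1L)
  ws$m <- as.integer(ws$m)
  ws$edge_i <- as.integer(graph$edges[, 1] - 1L)
  ws$edge_j <- as.integer(graph$edges[, 2] - 1L)
  ws$rank <- graph$n - graph$n_components
  ws$n_free <- sum(!ws$island)
  ws$use_lik <- use_likelihood
  ws$shared <- shared
  ws$a1 <- state$alpha[1]; ws$a2 <- state$alpha[2]
  ws$ld <- state$log_delta; ws$delta <- exp(state$log_delta)
  ws$th <- state$theta; ws$s1 <- state$s1; ws$s2 <- state$s2
  ws$u1 <- state$u1; ws$u2 <- state$u2
  ws$tau <- c(theta = state$tau_theta, s1 = state$tau_s1, s2 = state$tau_s2,
              u1 = state$tau_u1, u2 = state$tau_u2)
  .sync_lambda(ws)
  ws
}

.sync_lambda <- function(ws) {
  ws$lam1 <- ws$e1 * exp(ws$a1 + ws$delta * ws$th + ws$s1 + ws$u1)
  ws$lam2 <- ws$e2 * exp(ws$a2 + ws$th / ws$delta + ws$s2 + ws$u2)
  invisible(ws)
}

.ws_state <- function(ws) {
  model_state(alpha = c(ws$a1, ws$a2), log_delta = ws$ld,
              theta = ws$th, s1 = ws$s1, s2 = ws$s2, u1 = ws$u1, u2 = ws$u2,
              tau_theta = ws$tau[["theta"]], tau_s1 = ws$tau[["s1"]],
              tau_s2 = ws$tau[["s2"]], tau_u1 = ws$tau[["u1"]],
              tau_u2 = ws$tau[["u2"]])
}

.ws_deviance <- function(ws) {
  lam1 <- ws$e1 * exp(ws$a1 + ws$delta * ws$th + ws$s1 + ws$u1)
  lam2 <- ws$e2 * exp(ws$a2 + ws$th / ws$delta + ws$s2 + ws$u2)
  -2 * (sum(ws$O1 * log(lam1) - lam1 - lgamma(ws$O1 + 1)) +
          sum(ws$O2 * log(lam2) - lam2 - lgamma(ws$O2 + 1)))
}

# One full single-site Metropolis sweep over `field` (compiled kernel).
# Colour classes are updated in turn; within a class no two areas are
# neighbours, so the element-wise accept/reject is identical to
# sequential single-site updates.
.mh_field_sweep <- function(ws, field, scale) {
  code <- match(field, c("theta", "s1", "s2", "u1", "u2")) - 1L
  xname <- if (field == "theta") "th" else field
  res <- cpp_field_sweep(ws[[xname]], code, ws$tau[[field]], ws$delta,
                         scale, ws$use_lik, ws$lam1, ws$lam2, ws$O1, ws$O2,
                         ws$m, ws$nbr_ptr, ws$nbr_idx, ws$colours,
                         ws$island)
  ws[[xname]] <- res$x
  ws$lam1 <- res$lam1
  ws$lam2 <- res$lam2
  res$accept
}

# Random-walk Metropolis on the intercepts and the log scaling parameter.
# Returns named logical acceptance indicators.
.mh_scalar_sweep <- function(ws, priors, scales) {
  acc <- c(alpha1 = FALSE, alpha2 = FALSE, log_delta = NA)
  # alpha1
  da <- stats::rnorm(1, 0, scales[["alpha1"]])
  dpr <- stats::dnorm(ws$a1 + da, 0, priors$alpha_sd, log = TRUE) -
    stats::dnorm(ws$a1, 0, priors$alpha_sd, log = TRUE)
  dll <- if (ws$use_lik) sum(ws$O1) * da - sum(ws$lam1) * expm1(da) else 0
  if (log(stats::runif(1)) < dpr + dll) {
    ws$a1 <- ws$a1 + da
    ws$lam1 <- ws$lam1 * exp(da)
    acc[["alpha1"]] <- TRUE
  }
  # alpha2
  da <- stats::rnorm(1, 0, scales[["alpha2"]])
  dpr <- stats::dnorm(ws$a2 + da, 0, priors$alpha_sd, log = TRUE) -
    stats::dnorm(ws$a2, 0, priors$alpha_sd, log = TRUE)
  dll <- if (ws$use_lik) sum(ws$O2) * da - sum(ws$lam2) * expm1(da) else 0
  if (log(stats::runif(1)) < dpr + dll) {
    ws$a2 <- ws$a2 + da
    ws$lam2 <- ws$lam2 * exp(da)
    acc[["alpha2"]] <- TRUE
  }
  # log delta: rescales the shared surface's contribution to both outcomes
  if (ws$shared) {
    acc[["log_delta"]] <- .mh_log_delta(ws, priors, scales[["log_delta"]])
  }
  acc
}

.mh_log_delta <- function(ws, priors, scale) {
  dl <- stats::rnorm(1, 0, scale)
  ldp <- ws$ld + dl
  deltap <- exp(ldp)
  prec <- priors$log_delta_precision
  dpr <- -prec / 2 * ((ldp - priors$log_delta_mean)^2 -
                        (ws$ld - priors$log_delta_mean)^2)
  dll <- 0
  if (ws$use_lik) {
    d1 <- (deltap - ws$delta) * ws$th
    d2 <- (1 / deltap - 1 / ws$delta) * ws$th
    dll <- sum(ws$O1 * d1 - ws$lam1 * expm1(d1)) +
      sum(ws$O2 * d2 - ws$lam2 * expm1(d2))
  }
  if (is.finite(dll) && log(stats::runif(1)) < dpr + dll) {
    if (ws$use_lik) {
      ws$lam1 <- ws$lam1 * exp((deltap - ws$delta) * ws$th)
      ws$lam2 <- ws$lam2 * exp((1 / deltap - 1 / ws$delta) * ws$th)
    }
    ws$ld <- ldp
    ws$delta <- deltap
    return(TRUE)
  }
  FALSE
}

# Joint scale moves.  Single-site updates mix slowly along two nearly flat
# directions of this posterior: (i) growing the shared surface while
# shrinking the scaling parameter so the outcome-1 contribution delta*theta
# is unchanged, and (ii) the funnel between a field and its own precision.
# Both are handled by deterministic rescaling proposals driven by a
# symmetric normal increment, with the Jacobian term in the ratio.

# (log_delta, theta) -> (log_delta + dl, theta * exp(-dl)): outcome-1
# likelihood is exactly invariant; outcome 2, the ICAR quadratic and the
# log-delta prior decide acceptance.  log|J| = -n_free * dl.
.rescale_shared <- function(ws, priors, scale) {
  dl <- stats::rnorm(1, 0, scale)
  n_free <- sum(!ws$island)
  e <- ws$graph$edges
  E <- if (nrow(e)) sum((ws$th[e[, 1]] - ws$th[e[, 2]])^2) else 0
  fac <- expm1(-2 * dl)
  d_quad <- -ws$tau[["theta"]] / 2 * E * fac
  prec <- priors$log_delta_precision
  d_ld <- -prec / 2 * ((ws$ld + dl - priors$log_delta_mean)^2 -
                         (ws$ld - priors$log_delta_mean)^2)
  dll <- 0
  d2 <- (ws$th / ws$delta) * fac
  if (ws$use_lik) dll <- sum(ws$O2 * d2 - ws$lam2 * expm1(d2))
  if (log(stats::runif(1)) < d_quad + d_ld + dll - n_free * dl) {
    ws$th[!ws$island] <- ws$th[!ws$island] * exp(-dl)
    ws$ld <- ws$ld + dl
    ws$delta <- exp(ws$ld)
    ws$lam2 <- ws$lam2 * exp(d2)
    return(TRUE)
  }
  FALSE
}

# Shared/specific transfer: delta -> delta*exp(dl) with both specific
# surfaces compensating (s1 absorbs the outcome-1 change of delta*theta,
# s2 the outcome-2 change of theta/delta), so the likelihood is exactly
# invariant and the ICAR priors on s1, s2 plus the log-delta prior decide
# acceptance.  This targets the confounding between the shared and the
# outcome-specific surfaces, the slowest-mixing direction of the model.
.transfer_shared <- function(ws, priors, scale) {
  dl <- stats::rnorm(1, 0, scale)
  a <- ws$delta * expm1(dl)        # s1' = s1 - a*theta
  b <- expm1(-dl) / ws$delta       # s2' = s2 - b*theta
  e <- ws$graph$edges
  dth <- ws$th[e[, 1]] - ws$th[e[, 2]]
  Qt <- sum(dth^2)
  B1 <- sum((ws$s1[e[, 1]] - ws$s1[e[, 2]]) * dth)
  B2 <- sum((ws$s2[e[, 1]] - ws$s2[e[, 2]]) * dth)
  dQ1 <- -2 * a * B1 + a^2 * Qt
  dQ2 <- -2 * b * B2 + b^2 * Qt
  prec <- priors$log_delta_precision
  d_ld <- -prec / 2 * ((ws$ld + dl - priors$log_delta_mean)^2 -
                         (ws$ld - priors$log_delta_mean)^2)
  lr <- -ws$tau[["s1"]] / 2 * dQ1 - ws$tau[["s2"]] / 2 * dQ2 + d_ld
  if (log(stats::runif(1)) < lr) {
    ws$s1 <- ws$s1 - a * ws$th
    ws$s2 <- ws$s2 - b * ws$th
    ws$ld <- ws$ld + dl
    ws$delta <- exp(ws$ld)
    return(TRUE)
  }
  FALSE
}

# Two further likelihood-invariant kernels spanning the plane of the
# scaling parameter and the shared surface's magnitude.  Both scale theta
# and tau_theta together (leaving the shared ICAR prior's quadratic form
# invariant) while delta moves so that one outcome's shared contribution
# is unchanged and the other outcome's change is absorbed into its
# specific surface.
#   to_s1: delta, theta both * exp(dl); theta/delta invariant; s1 absorbs.
#   to_s2: delta * exp(-dl), theta * exp(dl); delta*theta invariant;
#          s2 absorbs.
.transfer_scale <- function(ws, priors, scale, target) {
  dl <- stats::rnorm(1, 0, scale)
  e <- ws$graph$edges
  dth <- ws$th[e[, 1]] - ws$th[e[, 2]]
  Qt <- sum(dth^2)
  rank <- ws$n - ws$graph$n_components
  n_free <- sum(!ws$island)
  ab <- priors$tau_theta
  tau_t <- ws$tau[["theta"]]
  d_tau <- (ab[1] - 1) * (-2 * dl) - ab[2] * tau_t * expm1(-2 * dl)
  prec <- priors$log_delta_precision
  sgn <- if (target == "s1") 1 else -1   # sign of the delta move
  d_ld <- -prec / 2 * ((ws$ld + sgn * dl - priors$log_delta_mean)^2 -
                         (ws$ld - priors$log_delta_mean)^2)
  if (target == "s1") {
    k <- ws$delta * expm1(2 * dl)        # s1' = s1 - k*theta
    B <- sum((ws$s1[e[, 1]] - ws$s1[e[, 2]]) * dth)
    tau_s <- ws$tau[["s1"]]
  } else {
    k <- expm1(2 * dl) / ws$delta        # s2' = s2 - k*theta
    B <- sum((ws$s2[e[, 1]] - ws$s2[e[, 2]]) * dth)
    tau_s <- ws$tau[["s2"]]
  }
  d_s <- -tau_s / 2 * (-2 * k * B + k^2 * Qt)
  lr <- -rank * dl + d_tau + d_ld + d_s + (n_free - 2) * dl
  if (log(stats::runif(1)) < lr) {
    th_old <- ws$th
    ws$th[!ws$island] <- th_old[!ws$island] * exp(dl)
    ws$tau[["theta"]] <- tau_t * exp(-2 * dl)
    if (target == "s1") ws$s1 <- ws$s1 - k * th_old
    else ws$s2 <- ws$s2 - k * th_old
    ws$ld <- ws$ld + sgn * dl
    ws$delta <- exp(ws$ld)
    return(TRUE)
  }
  FALSE
}

# Pattern-mixing kernel: shear a reference pattern w (one of the specific
# surfaces) into the shared surface with both outcomes exactly
# compensated:
#   theta += g*w,  s1 -= delta*g*w,  s2 -= g*w/delta.
# The likelihood is invariant and the Jacobian is 1 (a shear), so the
# three ICAR priors decide acceptance.  This moves the spatial alignment
# between the shared and specific surfaces -- a direction no single-site
# or scale move traverses quickly.
.mix_fields <- function(ws, scale, w_field) {
  g <- stats::rnorm(1, 0, scale)
  e <- ws$graph$edges
  w <- ws[[w_field]]
  dw <- w[e[, 1]] - w[e[, 2]]
  Qw <- sum(dw^2)
  if (Qw == 0) return(FALSE)
  Bt <- sum((ws$th[e[, 1]] - ws$th[e[, 2]]) * dw)
  B1 <- sum((ws$s1[e[, 1]] - ws$s1[e[, 2]]) * dw)
  B2 <- sum((ws$s2[e[, 1]] - ws$s2[e[, 2]]) * dw)
  c1 <- -ws$delta * g
  c2 <- -g / ws$delta
  lr <- -ws$tau[["theta"]] / 2 * (2 * g * Bt + g^2 * Qw) -
    ws$tau[["s1"]] / 2 * (2 * c1 * B1 + c1^2 * Qw) -
    ws$tau[["s2"]] / 2 * (2 * c2 * B2 + c2^2 * Qw)
  if (log(stats::runif(1)) < lr) {
    ws$th <- ws$th + g * w
    ws$s1 <- ws$s1 + c1 * w
    ws$s2 <- ws$s2 + c2 * w
    return(TRUE)
  }
  FALSE
}

# (x, tau) -> (x * exp(c), tau * exp(-2c)): the prior quadratic form is
# exactly invariant; the prior normalizer, the Gamma hyperprior, the
# likelihood and log|J| = n_free*c - 2c decide acceptance.
.rescale_field <- function(ws, field, priors, scale) {
  cc <- stats::rnorm(1, 0, scale)
  spatial <- field %in% c("theta", "s1", "s2")
  xname <- switch(field, theta = "th", field)
  x <- ws[[xname]]
  free <- if (spatial) !ws$island else rep(TRUE, ws$n)
  n_free <- sum(free)
  rank <- if (spatial) ws$n - ws$graph$n_components else ws$n
  tau <- ws$tau[[field]]
  ab <- priors[[paste0("tau_", field)]]
  d_norm <- -rank * cc                      # (rank/2) * (log tau' - log tau)
  d_gam <- (ab[1] - 1) * (-2 * cc) - ab[2] * tau * expm1(-2 * cc)
  g <- expm1(cc)
  dll <- 0
  d1 <- d2 <- NULL
  if (ws$use_lik) {
    if (field == "theta") {
      d1 <- ws$delta * x * g
      d2 <- x * g / ws$delta
      dll <- sum(ws$O1 * d1 - ws$lam1 * expm1(d1)) +
        sum(ws$O2 * d2 - ws$lam2 * expm1(d2))
    } else if (field %in% c("s1", "u1")) {
      d1 <- x * g
      dll <- sum(ws$O1 * d1 - ws$lam1 * expm1(d1))
    } else {
      d2 <- x * g
      dll <- sum(ws$O2 * d2 - ws$lam2 * expm1(d2))
    }
  }
  if (is.finite(dll) &&
      log(stats::runif(1)) < d_norm + d_gam + dll + n_free * cc - 2 * cc) {
    x[free] <- x[free] * exp(cc)
    ws[[xname]] <- x
    ws$tau[[field]] <- tau * exp(-2 * cc)
    if (ws$use_lik) {
      if (!is.null(d1)) ws$lam1 <- ws$lam1 * exp(d1)
      if (!is.null(d2)) ws$lam2 <- ws$lam2 * exp(d2)
    } else {
      .sync_lambda(ws)
    }
    return(TRUE)
  }
  FALSE
}

.ws_recenter <- function(ws) {
  mt <- mean(ws$th); m1 <- mean(ws$s1); m2 <- mean(ws$s2)
  ws$th <- ws$th - mt
  ws$s1 <- ws$s1 - m1
  ws$s2 <- ws$s2 - m2
  ws$a1 <- ws$a1 + ws$delta * mt + m1
  ws$a2 <- ws$a2 + mt / ws$delta + m2
  invisible(ws)
}

#' One Metropolis sweep over a latent field
#'
#' Updates every element of the named field by single-site random-walk
#' Metropolis under the Poisson likelihood and the field's prior (ICAR for
#' the spatial surfaces, zero-mean normal for the unstructured effects).
#' Island areas of spatial fields are pinned at zero and skipped (`NA` in
#' the acceptance vector).
#'
#' @param field_name One of `"theta"`, `"s1"`, `"s2"`, `"u1"`, `"u2"`.
#' @param state A [model_state].
#' @param table,expected Data as in [log_likelihood].
#' @param graph An [areal_graph].
#' @param scale Proposal standard deviation (> 0).
#' @param use_likelihood Set `FALSE` to target the prior alone.
#' @return List with the updated `state` and logical `accept` per element.
#' @export
mh_update_field <- function(field_name, state, table, expected, graph,
                            scale, use_likelihood = TRUE) {
  stopifnot(scale > 0,
            field_name %in% c("theta", "s1", "s2", "u1", "u2"))
  ws <- .make_workspace(state, table, expected, graph,
                        use_likelihood = use_likelihood)
  accept <- .mh_field_sweep(ws, field_name, scale)
  list(state = .ws_state(ws), accept = accept)
}

#' One Metropolis sweep over the scalar parameters
#'
#' Random-walk Metropolis on both intercepts and on the log scaling
#' parameter; the scaling move re-weights the shared surface's contribution
#' to both outcomes inside the acceptance ratio.
#'
#' @inheritParams mh_update_field
#' @param priors A [prior_spec].
#' @param scales Named proposal standard deviations
#'   (`alpha1`, `alpha2`, `log_delta`), all positive.
#' @return List with the updated `state` and named logical `accept`.
#' @export
mh_update_scalars <- function(state, table, expected, priors, graph,
                              scales = c(alpha1 = 0.05, alpha2 = 0.05,
                                         log_delta = 0.2),
                              use_likelihood = TRUE) {
  stopifnot(all(scales > 0))
  ws <- .make_workspace(state, table, expected, graph,
                        use_likelihood = use_likelihood)
  acc <- .mh_scalar_sweep(ws, priors, scales)
  list(state = .ws_state(ws), accept = acc)
}

#' Run the Metropolis-within-Gibbs sampler
#'
#' Each iteration sweeps, in fixed order: the shared surface, both specific
#' surfaces, both unstructured fields (single-site random-walk Metropolis),
#' the intercepts and log scaling parameter (scalar Metropolis), conjugate
#' Gibbs draws for the five precisions, joint scale moves (a
#' shared-surface/scaling-parameter rescaling and field/precision
#' rescalings, which traverse the posterior's nearly flat directions), and
#' a recentering projection that keeps the improper spatial surfaces
#' identified against the intercepts.
#' Proposal scales adapt by Robbins-Monro toward the target acceptance rate
#' during burn-in only, then freeze, so the post-burn-in chain has the
#' correct stationary distribution.
#'
#' @param config An [mcmc_config].
#' @param table An annualized [outcome_table] in graph order.
#' @param expected Matching [compute_expected] result.
#' @param priors A [prior_spec].
#' @param graph An [areal_graph].
#' @param use_likelihood Set `FALSE` to sample the prior alone
#'   (calibration checks).
#' @param shared Set `FALSE` to fit the no-shared-component variant (the
#'   shared surface pinned at zero and the scaling parameter fixed at 1:
#'   two independent convolution models); used for DIC comparison.
#' @return An object of class `scsm_samples`: per chain, a matrix `scalars`
#'   (columns `alpha1`, `alpha2`, `log_delta`, the five precisions and
#'   `deviance`) and draw-by-area matrices `theta`, `s1`, `s2`, `u1`, `u2`;
#'   plus the retained iteration indices, per-block post-burn-in acceptance
#'   rates, adapted scales, and run metadata.
#' @export
run_mcmc <- function(config, table, expected, priors, graph,
                     use_likelihood = TRUE, shared = TRUE) {
  stopifnot(inherits(config, "mcmc_config"), inherits(priors, "prior_spec"),
            inherits(graph, "areal_graph"))
  py <- period_years(table)
  if (any(py != 1)) {
    stop("table must be annualized (period_years = 1) before fitting; ",
         "call annualize_counts()")
  }
  n_kept <- (config$iterations - config$burn_in) %/% config$thinning
  kept_iter <- config$burn_in + config$thinning * seq_len(n_kept)
  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, config$chains)
  fields <- c("theta", "s1", "s2", "u1", "u2")
  upd_fields <- if (shared) fields else setdiff(fields, "theta")
  any_island <- any(graph$m == 0L)
  hyper <- list(theta = priors$tau_theta, s1 = priors$tau_s1,
                s2 = priors$tau_s2, u1 = priors$tau_u1, u2 = priors$tau_u2)

  chains <- vector("list", config$chains)
  acc_report <- vector("list", config$chains)
  scale_report <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    set.seed(chain_seeds[ch])
    state0 <- init_state(table, expected, priors)
    ws <- .make_workspace(state0, table, expected, graph,
                          use_likelihood = use_likelihood, shared = shared)
    lp0 <- log_posterior(.ws_state(ws), table, expected, priors, graph)
    if (!is.finite(lp0)) stop("non-finite log-posterior at initialization")
    scales <- config$scales
    blocks <- c(upd_fields, "alpha1", "alpha2", if (shared) "log_delta",
                if (shared) c("shared_scale", "theta_scale",
                              "shared_transfer", "transfer_s1",
                              "transfer_s2", "mix_s1", "mix_s2"),
                "s1_scale", "s2_scale", "u1_scale", "u2_scale")
    win_acc <- win_att <- setNames(numeric(length(blocks)), blocks)
    post_acc <- post_att <- setNames(numeric(length(blocks)), blocks)
    adapt_step <- 0L

    scal <- matrix(NA_real_, n_kept, 9,
                   dimnames = list(NULL, c("alpha1", "alpha2", "log_delta",
                                           "tau_theta", "tau_s1", "tau_s2",
                                           "tau_u1", "tau_u2", "deviance")))
    fld <- lapply(setNames(fields, fields), function(f)
      matrix(NA_real_, n_kept, ws$n, dimnames = list(NULL, graph$area_ids)))
    hyp_mat <- rbind(priors$tau_theta, priors$tau_s1, priors$tau_s2,
                     priors$tau_u1, priors$tau_u2)
    kk <- 0L
    for (it in seq_len(config$iterations)) {
      in_burn <- it <= config$burn_in
      # one compiled sweep: `field_sweeps` scans of all fields and
      # scalars, then `delta_substeps` repetitions of the hyperparameter
      # block (precision Gibbs draws + scale/transfer/mixing kernels)
      res <- cpp_scsm_iterate(ws$th, ws$s1, ws$s2, ws$u1, ws$u2,
                              ws$a1, ws$a2, ws$ld, ws$tau,
                              ws$lam1, ws$lam2, ws$O1, ws$O2,
                              ws$m, ws$nbr_ptr, ws$nbr_idx, ws$colours,
                              ws$edge_i, ws$edge_j, ws$island,
                              ws$use_lik, shared, config$field_sweeps,
                              config$delta_substeps,
                              scales[.block_order],
                              priors$alpha_sd, priors$log_delta_mean,
                              priors$log_delta_precision, hyp_mat,
                              ws$rank, ws$n_free)
      ws$th <- res$th; ws$s1 <- res$s1; ws$s2 <- res$s2
      ws$u1 <- res$u1; ws$u2 <- res$u2
      ws$a1 <- res$a1; ws$a2 <- res$a2
      ws$ld <- res$ld; ws$delta <- exp(res$ld)
      tau <- res$tau; names(tau) <- names(ws$tau)
      ws$tau <- tau
      ws$lam1 <- res$lam1; ws$lam2 <- res$lam2
      if (in_burn) {
        win_acc <- win_acc + res$acc[.block_idx(blocks)]
        win_att <- win_att + res$att[.block_idx(blocks)]
      } else {
        post_acc <- post_acc + res$acc[.block_idx(blocks)]
        post_att <- post_att + res$att[.block_idx(blocks)]
      }
      if (!any_island) .ws_recenter(ws)
      if (it %% 200L == 0L) .sync_lambda(ws)

      if (in_burn && it %% config$adapt_window == 0L) {
        adapt_step <- adapt_step + 1L
        gain <- 1 / sqrt(adapt_step)
        for (b in blocks) {
          if (win_att[[b]] > 0) {
            rate <- win_acc[[b]] / win_att[[b]]
            scales[[b]] <- min(10, max(1e-4, scales[[b]] *
                                         exp(gain * (rate - config$target_acceptance))))
          }
          win_acc[[b]] <- 0; win_att[[b]] <- 0
        }
      }
      if (!in_burn && (it - config$burn_in) %% config$thinning == 0L) {
        kk <- kk + 1L
        scal[kk, ] <- c(ws$a1, ws$a2, ws$ld, ws$tau[["theta"]],
                        ws$tau[["s1"]], ws$tau[["s2"]], ws$tau[["u1"]],
                        ws$tau[["u2"]], .ws_deviance(ws))
        for (f in fields) fld[[f]][kk, ] <- ws[[switch(f, theta = "th",
                                                       s1 = "s1", s2 = "s2",
                                                       u1 = "u1", u2 = "u2")]]
      }
    }
    chains[[ch]] <- c(list(scalars = scal), fld)
    acc_report[[ch]] <- ifelse(post_att > 0, post_acc / post_att, NA)
    scale_report[[ch]] <- scales
  }
  structure(list(chains = chains, iterations = kept_iter,
                 acceptance = acc_report, scales = scale_report,
                 config = config, priors = priors, shared = shared,
                 use_likelihood = use_likelihood,
                 area_ids = graph$area_ids),
            class = "scsm_samples")
}

#' @export
print.scsm_samples <- function(x, ...) {
  cat("scsm_samples:", length(x$chains), "chain(s) x",
      nrow(x$chains[[1]]$scalars), "draws,", length(x$area_ids), "areas",
      if (!x$shared) "(no shared component)", "\n")
  invisible(x)
}

#' Pooled draws of a monitored quantity
#'
#' @param samples An `scsm_samples` object.
#' @param parameter A scalar column name (`"alpha1"`, `"log_delta"`,
#'   `"tau_theta"`, `"deviance"`, ...) or a field name (`"theta"`, `"s1"`,
#'   ...), in which case `area` selects the column.
#' @param area Optional area index or id for field parameters.
#' @return Numeric vector of draws pooled across chains.
#' @export
pooled_draws <- function(samples, parameter, area = NULL) {
  pull <- function(chain) {
    if (parameter %in% colnames(chain$scalars)) {
      chain$scalars[, parameter]
    } else if (parameter %in% names(chain)) {
      if (is.null(area)) stop("area required for field parameter")
      chain[[parameter]][, area]
    } else {
      stop("unknown parameter: ", parameter)
    }
  }
  unlist(lapply(samples$chains, pull), use.names = FALSE)
}

#' Write / read posterior samples as long-format CSV
#'
#' Columns `chain`, `iteration`, `parameter`, `value`; field elements are
#' named `theta[area_id]` etc.  The reader reconstructs an `scsm_samples`
#' object (run metadata other than the retained iterations is not
#' round-tripped).
#'
#' @param samples An `scsm_samples` object.
#' @param path CSV path.
#' @return `write_samples` returns `path` invisibly; `read_samples` an
#'   `scsm_samples` object.
#' @export
write_samples <- function(samples, path) {
  rows <- lapply(seq_along(samples$chains), function(ch) {
    cc <- samples$chains[[ch]]
    wide <- cbind(cc$scalars,
                  do.call(cbind, lapply(c("theta", "s1", "s2", "u1", "u2"),
                    function(f) {
                      m <- cc[[f]]
                      colnames(m) <- paste0(f, "[", colnames(m), "]")
                      m
                    })))
    data.frame(chain = ch,
               iteration = rep(samples$iterations, ncol(wide)),
               parameter = rep(colnames(wide), each = nrow(wide)),
               value = as.vector(wide), stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  iters <- sort(unique(df$iteration))
  fields <- c("theta", "s1", "s2", "u1", "u2")
  chains <- lapply(sort(unique(df$chain)), function(ch) {
    d <- df[df$chain == ch, ]
    pars <- unique(d$parameter)
    wide <- sapply(pars, function(p) d$value[d$parameter == p])
    is_field <- grepl("^(theta|s1|s2|u1|u2)\\[", pars)
    out <- list(scalars = wide[, pars[!is_field], drop = FALSE])
    for (f in fields) {
      sel <- grepl(paste0("^", f, "\\["), pars)
      m <- wide[, pars[sel], drop = FALSE]
      colnames(m) <- sub("^[a-z0-9]+\\[(.*)\\]$", "\\1", pars[sel])
      out[[f]] <- m
    }
    out
  })
  area_ids <- colnames(chains[[1]]$theta)
  structure(list(chains = chains, iterations = iters, acceptance = NULL,
                 scales = NULL, config = NULL, priors = NULL, shared = NA,
                 use_likelihood = NA, area_ids = area_ids),
            class = "scsm_samples")
}
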