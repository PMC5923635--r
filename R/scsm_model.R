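#' Model state of the shared-component spatial model
#'
#' The joint model for two areal count outcomes is, per area `i`:
#' \deqn{O_{i1} \sim Poisson(e_{i1} r_{1i}), \quad
#'       O_{i2} \sim Poisson(e_{i2} r_{2i})}
#' \deqn{r_{1i} = \exp(\alpha_1 + \delta\theta_i + s_{1i} + u_{1i}), \quad
#'       r_{2i} = \exp(\alpha_2 + \theta_i/\delta + s_{2i} + u_{2i})}
#' with a shared spatial surface `theta` entering both linear predictors
#' (scaled by `delta` for outcome 1 and `1/delta` for outcome 2),
#' outcome-specific ICAR surfaces `s1`, `s2`, and unstructured normal
#' effects `u1`, `u2`.  Precisions are the inverse variances of the five
#' random-effect ensembles.
#'
#' @param alpha Length-2 numeric: log-baseline risks.
#' @param log_delta Natural log of the scaling parameter (`delta > 0`).
#' @param theta,s1,s2,u1,u2 Numeric fields of common length `n`.
#' @param tau_theta,tau_s1,tau_s2,tau_u1,tau_u2 Positive precisions.
#' @return An object of class `model_state`.
#' @export
model_state <- function(alpha = c(0, 0), log_delta = 0,
                        theta, s1 = 0 * theta, s2 = 0 * theta,
                        u1 = 0 * theta, u2 = 0 * theta,
                        tau_theta = 1, tau_s1 = 1, tau_s2 = 1,
                        tau_u1 = 1, tau_u2 = 1) {
  n <- length(theta)
  stopifnot(length(alpha) == 2, length(log_delta) == 1,
            length(s1) == n, length(s2) == n,
            length(u1) == n, length(u2) == n)
  taus <- c(tau_theta, tau_s1, tau_s2, tau_u1, tau_u2)
  if (any(!is.finite(taus)) || any(taus <= 0)) {
    stop("all precisions must be positive and finite")
  }
  structure(list(alpha = as.numeric(alpha),
                 log_delta = as.numeric(log_delta),
                 theta = as.numeric(theta), s1 = as.numeric(s1),
                 s2 = as.numeric(s2), u1 = as.numeric(u1),
                 u2 = as.numeric(u2),
                 tau_theta = tau_theta, tau_s1 = tau_s1, tau_s2 = tau_s2,
                 tau_u1 = tau_u1, tau_u2 = tau_u2),
            class = "model_state")
}

#' Deterministic initial state
#'
#' All fields zero, intercepts at the log observed/expected ratio (zero
#' under internal standardization), log scaling parameter zero, precisions
#' at their hyperprior means.
#'
#' @param table An annualized [outcome_table].
#' @param expected Matching [compute_expected] result.
#' @param priors A [prior_spec].
#' @return A [model_state].
#' @export
init_state <- function(table, expected, priors) {
  n <- nrow(table)
  a1 <- log(sum(table$O1) / sum(expected$e[, 1]))
  a2 <- log(sum(table$O2) / sum(expected$e[, 2]))
  gm <- function(ab) ab[1] / ab[2]
  model_state(alpha = c(a1, a2), log_delta = 0, theta = numeric(n),
              tau_theta = gm(priors$tau_theta), tau_s1 = gm(priors$tau_s1),
              tau_s2 = gm(priors$tau_s2), tau_u1 = gm(priors$tau_u1),
              tau_u2 = gm(priors$tau_u2))
}

#' Per-area relative risks implied by a state
#'
#' @param state A [model_state].
#' @return An `n x 2` matrix: column 1 is
#'   `exp(alpha1 + delta*theta + s1 + u1)`, column 2 is
#'   `exp(alpha2 + theta/delta + s2 + u2)`.
#' @export
relative_risks <- function(state) {
  delta <- exp(state$log_delta)
  r <- cbind(exp(state$alpha[1] + delta * state$theta + state$s1 + state$u1),
             exp(state$alpha[2] + state$theta / delta + state$s2 + state$u2))
  colnames(r) <- c("r1", "r2")
  r
}

#' Poisson log-likelihood of the observed counts
#'
#' `sum over areas and outcomes of O*log(lambda) - lambda - lgamma(O+1)`
#' with `lambda = e * r`.  The log-gamma form extends the Poisson
#' log-density continuously to non-integral counts (annual averages of
#' multi-year counts).
#'
#' @param state A [model_state].
#' @param table An [outcome_table].
#' @param expected Matching [compute_expected] result.
#' @return The scalar log-likelihood.
#' @export
log_likelihood <- function(state, table, expected) {
  O <- cbind(table$O1, table$O2)
  lam <- expected$e * relative_risks(state)
  if (any(!is.finite(lam) | lam <= 0)) {
    bad <- which(!is.finite(lam) | lam <= 0, arr.ind = TRUE)[1, ]
    stop("non-finite or non-positive Poisson mean for area ",
         table$area_id[bad[1]], ", outcome ", bad[2])
  }
  sum(O * log(lam) - lam - lgamma(O + 1))
}

#' Model deviance
#'
#' `-2 * log_likelihood`; the quantity monitored per MCMC draw and
#' plugged into the DIC.
#'
#' @inheritParams log_likelihood
#' @return Scalar deviance.
#' @export
deviance_scsm <- function(state, table, expected) {
  -2 * log_likelihood(state, table, expected)
}

#' ICAR joint log-density (pairwise-difference form)
#'
#' Improper Gaussian Markov random field prior over a field `x`:
#' \deqn{((n - c)/2)\log\tau - (\tau/2)\sum_{i \sim j}(x_i - x_j)^2}
#' summing over unordered neighbour pairs, where `c` is the number of
#' connected components (the rank deficiency of the graph Laplacian).
#' Defined up to an additive constant; exactly invariant to adding a
#' constant per component.
#'
#' @param x Numeric field of length `n`.
#' @param graph An [areal_graph].
#' @param tau Positive precision.
#' @return Scalar unnormalized log-density.
#' @export
icar_pairwise_log_density <- function(x, graph, tau) {
  stopifnot(length(x) == graph$n, tau > 0)
  e <- graph$edges
  quad <- if (nrow(e)) sum((x[e[, 1]] - x[e[, 2]])^2) else 0
  ((graph$n - graph$n_components) / 2) * log(tau) - (tau / 2) * quad
}

#' ICAR full conditional of one area
#'
#' Given its neighbours, an area's effect is normal with mean the average
#' of the neighbouring values and variance `1/(tau * m_i)`.
#'
#' @param i Area index (canonical order).
#' @param x The current field.
#' @param graph An [areal_graph].
#' @param tau Positive precision.
#' @return List with elements `mean` and `variance`.
#' @export
icar_full_conditional <- function(i, x, graph, tau) {
  stopifnot(length(x) == graph$n, tau > 0, i >= 1, i <= graph$n)
  if (graph$m[i] == 0) {
    stop("area ", graph$area_ids[i],
         " has no neighbours: ICAR conditional undefined (island effects",
         " are pinned to 0 upstream)")
  }
  e <- graph$edges
  nb <- c(e[e[, 1] == i, 2], e[e[, 2] == i, 1])
  list(mean = mean(x[nb]), variance = 1 / (tau * graph$m[i]))
}

#' Joint log-prior of a model state
#'
#' Sum of: near-flat normal terms for both intercepts; the normal prior on
#' the log scaling parameter; ICAR terms for the shared and the two
#' specific surfaces; zero-mean normal terms for the unstructured effects;
#' and Gamma (shape/rate) terms for the five precisions.
#'
#' @param state A [model_state].
#' @param priors A [prior_spec].
#' @param graph An [areal_graph].
#' @return Scalar log-prior (up to the ICAR improper constants).
#' @export
log_prior <- function(state, priors, graph) {
  n <- graph$n
  lp <- sum(stats::dnorm(state$alpha, 0, priors$alpha_sd, log = TRUE))
  lp <- lp + stats::dnorm(state$log_delta, priors$log_delta_mean,
                          1 / sqrt(priors$log_delta_precision), log = TRUE)
  lp <- lp + icar_pairwise_log_density(state$theta, graph, state$tau_theta)
  lp <- lp + icar_pairwise_log_density(state$s1, graph, state$tau_s1)
  lp <- lp + icar_pairwise_log_density(state$s2, graph, state$tau_s2)
  lp <- lp + sum(stats::dnorm(state$u1, 0, 1 / sqrt(state$tau_u1), log = TRUE))
  lp <- lp + sum(stats::dnorm(state$u2, 0, 1 / sqrt(state$tau_u2), log = TRUE))
  for (nm in c("tau_theta", "tau_s1", "tau_s2", "tau_u1", "tau_u2")) {
    ab <- priors[[nm]]
    lp <- lp + stats::dgamma(state[[nm]], shape = ab[1], rate = ab[2],
                             log = TRUE)
  }
  lp
}

#' Joint unnormalized log-posterior
#'
#' @inheritParams log_likelihood
#' @param priors A [prior_spec].
#' @param graph An [areal_graph].
#' @return `log_likelihood + log_prior`.
#' @export
log_posterior <- function(state, table, expected, priors, graph) {
  log_likelihood(state, table, expected) + log_prior(state, priors, graph)
}
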