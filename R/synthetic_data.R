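#' Exact draw from an ICAR field
#'
#' Samples the intrinsic Gaussian Markov random field with precision
#' matrix `tau * L` (graph Laplacian `L`) restricted to the sum-to-zero
#' subspace of each connected component, by eigendecomposition of the
#' per-component Laplacian: the draw is
#' `sum_j v_j z_j / sqrt(tau * lambda_j)` over the positive eigenpairs.
#' Being independent of the MCMC machinery, it serves as the reference
#' sampler in prior-equivalence checks.  Components of size one (islands)
#' get a zero entry.
#'
#' @param graph An [areal_graph].
#' @param tau Positive precision.
#' @param seed Optional integer seed (otherwise the current RNG stream is
#'   used).
#' @return A field of length `n`, summing to zero within each component.
#' @export
sample_icar_field <- function(graph, tau, seed = NULL) {
  stopifnot(tau > 0)
  if (!is.null(seed)) set.seed(seed)
  x <- numeric(graph$n)
  L <- graph_laplacian(graph, dense = TRUE)
  for (comp in seq_len(graph$n_components)) {
    ix <- which(graph$component == comp)
    if (length(ix) == 1) next
    eig <- eigen(L[ix, ix, drop = FALSE], symmetric = TRUE)
    pos <- eig$values > max(eig$values) * 1e-10
    z <- rnorm(sum(pos))
    x[ix] <- eig$vectors[, pos, drop = FALSE] %*%
      (z / sqrt(tau * eig$values[pos]))
  }
  x
}

#' Random at-risk populations
#'
#' Integer populations uniform on `[low, high]`, defaulting to the
#' 7000--10,000 range typical of urban planning neighbourhoods.
#'
#' @param n Number of areas.
#' @param low,high Inclusive bounds, `0 < low <= high`.
#' @param seed Optional integer seed.
#' @return Integer vector of length `n`.
#' @export
generate_populations <- function(n, low = 7000, high = 10000, seed = NULL) {
  stopifnot(low > 0, low <= high)
  if (!is.null(seed)) set.seed(seed)
  low + sample.int(high - low + 1L, n, replace = TRUE) - 1L
}

#' Built-in simulation scenarios
#'
#' Parameter sets for [generate_dataset]:
#' \describe{
#'   \item{`shared_dominant`}{a strong shared surface
#'     (`tau_theta = 4`) with weak specific surfaces (`tau_s = 25`) and
#'     small unstructured noise (`tau_u = 400`), scaling `delta = 0.5`, so
#'     the shared component carries a steeper gradient for outcome 2;}
#'   \item{`discrepant`}{weak shared surface (`tau_theta = 100`), strong
#'     specific surfaces (`tau_s = 4`), `delta = 1`;}
#'   \item{`null`}{all random effects zero and `delta = 1`: counts are
#'     plain Poisson around the expected values.}
#' }
#' Baseline per-person annual rates default to 0.03 for outcome 1 and
#' 0.002 for outcome 2, giving expected counts of roughly 210--300 and
#' 14--20 per area at the default populations — a high-count outcome
#' (doctor-visit-like) paired with a low-count one (admission-like).
#'
#' @param scenario `"shared_dominant"`, `"discrepant"`, `"null"`, or
#'   `"custom"` (all parameters from `...`).
#' @param ... Overrides: `delta`, `tau_theta`, `tau_s1`, `tau_s2`,
#'   `tau_u1`, `tau_u2`, `alpha` (length 2), `rates` (length 2).
#' @return Named list of generator parameters.
#' @export
scenario_params <- function(scenario = c("shared_dominant", "discrepant",
                                         "null", "custom"), ...) {
  scenario <- match.arg(scenario)
  base <- switch(scenario,
    shared_dominant = list(delta = 0.5, tau_theta = 4, tau_s1 = 25,
                           tau_s2 = 25, tau_u1 = 400, tau_u2 = 400),
    discrepant = list(delta = 1, tau_theta = 100, tau_s1 = 4, tau_s2 = 4,
                      tau_u1 = 400, tau_u2 = 400),
    null = list(delta = 1, tau_theta = Inf, tau_s1 = Inf, tau_s2 = Inf,
                tau_u1 = Inf, tau_u2 = Inf),
    custom = list(delta = 1, tau_theta = 4, tau_s1 = 25, tau_s2 = 25,
                  tau_u1 = 400, tau_u2 = 400))
  base$alpha <- c(0, 0)
  base$rates <- c(0.03, 0.002)
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad)) stop("unknown scenario parameter(s): ",
                        paste(bad, collapse = ", "))
  base[names(over)] <- over
  base$scenario <- scenario
  base
}

#' Generate a synthetic dataset from the generative model
#'
#' Runs the shared-component model forward on a graph: draws the shared
#' and specific surfaces as exact ICAR fields, unstructured effects as iid
#' normals, forms the Poisson means
#' `lambda[,1] = e1 * exp(alpha1 + delta*theta + s1 + u1)` (analogously
#' for outcome 2 with `1/delta`) from baseline rates times populations,
#' and draws Poisson counts.  With `min_count` set, any area with a count
#' below it has both its counts redrawn until the floor is met (emulating
#' a "no sparse areas" reporting floor).
#'
#' @param scenario A scenario name for [scenario_params], or a parameter
#'   list returned by it.
#' @param graph An [areal_graph] (default the 14 x 10 queen lattice,
#'   n = 140).
#' @param seed Integer seed; the dataset is reproducible from
#'   (scenario, graph, seed).
#' @param pop_range Length-2 population bounds.
#' @param min_count If not `NULL`, regenerate each area's counts until
#'   both outcomes reach this floor (e.g. 5).
#' @return List with `table` (an [outcome_table] of integer single-year
#'   counts) and `truth` (class `scsm_truth`): the generating
#'   [model_state], graph, populations, per-area expected counts used,
#'   scenario label and seed.
#' @export
generate_dataset <- function(scenario = "shared_dominant",
                             graph = grid_graph(14, 10, "queen"),
                             seed = 1, pop_range = c(7000, 10000),
                             min_count = NULL) {
  pars <- if (is.character(scenario)) scenario_params(scenario) else scenario
  stopifnot(is.list(pars), !is.null(pars$delta))
  set.seed(seed)
  n <- graph$n
  N <- generate_populations(n, pop_range[1], pop_range[2])
  e <- outer(as.numeric(N), pars$rates)
  draw_field <- function(tau) {
    if (is.infinite(tau)) numeric(n) else sample_icar_field(graph, tau)
  }
  theta <- draw_field(pars$tau_theta)
  s1 <- draw_field(pars$tau_s1)
  s2 <- draw_field(pars$tau_s2)
  u1 <- if (is.infinite(pars$tau_u1)) numeric(n)
        else rnorm(n, 0, 1 / sqrt(pars$tau_u1))
  u2 <- if (is.infinite(pars$tau_u2)) numeric(n)
        else rnorm(n, 0, 1 / sqrt(pars$tau_u2))
  fin <- function(x) if (is.infinite(x)) 1e12 else x
  state <- model_state(alpha = pars$alpha, log_delta = log(pars$delta),
                       theta = theta, s1 = s1, s2 = s2, u1 = u1, u2 = u2,
                       tau_theta = fin(pars$tau_theta),
                       tau_s1 = fin(pars$tau_s1), tau_s2 = fin(pars$tau_s2),
                       tau_u1 = fin(pars$tau_u1), tau_u2 = fin(pars$tau_u2))
  lam <- e * relative_risks(state)
  O1 <- rpois(n, lam[, 1])
  O2 <- rpois(n, lam[, 2])
  if (!is.null(min_count)) {
    for (i in seq_len(n)) {
      tries <- 0L
      while (O1[i] < min_count || O2[i] < min_count) {
        O1[i] <- rpois(1, lam[i, 1])
        O2[i] <- rpois(1, lam[i, 2])
        tries <- tries + 1L
        if (tries > 10000L) {
          stop("area ", graph$area_ids[i], ": count floor ", min_count,
               " unreachable (mean ", signif(min(lam[i, ]), 3), ")")
        }
      }
    }
  }
  table <- outcome_table(graph$area_ids, O1, O2, N)
  truth <- structure(list(state = state, graph = graph, N = N, e = e,
                          lambda = lam, scenario = pars$scenario %||% "custom",
                          seed = seed),
                     class = "scsm_truth")
  list(table = table, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the ground truth of a synthetic dataset as JSON
#'
#' @param truth An `scsm_truth` object from [generate_dataset].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  st <- truth$state
  jsonlite::write_json(
    list(scenario = truth$scenario, seed = truth$seed,
         n = truth$graph$n, area_ids = truth$graph$area_ids,
         alpha = st$alpha, delta = exp(st$log_delta),
         theta = st$theta, s1 = st$s1, s2 = st$s2, u1 = st$u1, u2 = st$u2,
         tau = c(theta = st$tau_theta, s1 = st$tau_s1, s2 = st$tau_s2,
                 u1 = st$tau_u1, u2 = st$tau_u2),
         N = truth$N, e = truth$e),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
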