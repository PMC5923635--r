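# Small graphs and datasets built in code for the tests.

path_graph <- function(n, ids = LETTERS[seq_len(n)]) {
  areal_graph(ids, cbind(ids[-n], ids[-1]))
}

random_graph <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  ids <- paste0("a", seq_len(n))
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  suppressWarnings(areal_graph(ids, cbind(ids[pairs[keep, 1]],
                                          ids[pairs[keep, 2]])))
}

# tiny annualized dataset on a graph, with simple Poisson counts
tiny_dataset <- function(graph, seed = 1, rate1 = 0.03, rate2 = 0.005) {
  set.seed(seed)
  n <- graph$n
  N <- generate_populations(n, 1000, 2000)
  O1 <- rpois(n, rate1 * N)
  O2 <- pmax(rpois(n, rate2 * N), 1)
  outcome_table(graph$area_ids, O1, O2, N)
}

quick_config <- function(seed = 1, iterations = 600, burn_in = 100,
                         thinning = 5, chains = 2, ...) {
  mcmc_config(chains = chains, iterations = iterations, burn_in = burn_in,
              thinning = thinning, seed = seed, field_sweeps = 2,
              delta_substeps = 4, ...)
}

# dense-matrix Laplacian oracle for ICAR quantities
dense_laplacian <- function(graph) {
  W <- as.matrix(adjacency_matrix(graph))
  diag(rowSums(W)) - W
}
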