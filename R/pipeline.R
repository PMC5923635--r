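#' Pipeline run configuration
#'
#' A single configuration drives the simulate -> fit -> summarize pipeline;
#' every stage writes a resolved copy of the configuration next to its
#' outputs for provenance.  Read from YAML or JSON with [read_run_config].
#'
#' @param out_dir Output directory (created if absent).
#' @param scenario Simulation scenario name (see [scenario_params]).
#' @param seed Master seed for the whole pipeline.
#' @param preset Hyperprior preset, `"held"` or `"ancelet"`, or `"both"`
#'   to fit and DIC-compare the two.
#' @param mcmc Named list of [mcmc_config] overrides
#'   (`chains`, `iterations`, `burn_in`, `thinning`).
#' @param graph_file,counts_file Optional paths to an existing adjacency
#'   file (GAL) and counts CSV; when `NULL` the simulate stage writes them
#'   under `out_dir`.
#' @param levels Credible-interval tail levels for summaries.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(out_dir, scenario = "shared_dominant", seed = 1,
                       preset = "held",
                       mcmc = list(chains = 2, iterations = 12000,
                                   burn_in = 2000, thinning = 5),
                       graph_file = NULL, counts_file = NULL,
                       levels = c(0.025, 0.975)) {
  structure(list(out_dir = out_dir, scenario = scenario,
                 seed = as.integer(seed), preset = preset, mcmc = mcmc,
                 graph_file = graph_file, counts_file = counts_file,
                 levels = levels),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML (`.yaml`/`.yml`) or JSON file.
#' @export
read_run_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x[intersect(names(x), names(formals(run_config)))])
}

.write_resolved_config <- function(config, stage) {
  path <- file.path(config$out_dir, paste0("config_", stage, ".yaml"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.pipeline_graph <- function(config) {
  if (!is.null(config$graph_file)) {
    read_adjacency(config$graph_file, "gal")
  } else {
    read_adjacency(file.path(config$out_dir, "graph.gal"), "gal")
  }
}

#' Simulate stage: write counts, graph and truth files
#'
#' Generates a synthetic dataset under the configured scenario and seed on
#' the default 14 x 10 queen lattice (or the graph in
#' `config$graph_file`), and writes `counts.csv`, `graph.gal` and
#' `truth.json` under `config$out_dir`.
#'
#' @param config A [run_config].
#' @return Invisibly, the list of written file paths.
#' @export
run_simulate <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  graph <- if (!is.null(config$graph_file)) {
    read_adjacency(config$graph_file, "gal")
  } else {
    grid_graph(14, 10, "queen")
  }
  sim <- generate_dataset(config$scenario, graph = graph, seed = config$seed)
  paths <- list(counts = file.path(config$out_dir, "counts.csv"),
                graph = file.path(config$out_dir, "graph.gal"),
                truth = file.path(config$out_dir, "truth.json"))
  write_counts(sim$table, paths$counts)
  write_adjacency(graph, paths$graph, "gal")
  write_truth(sim$truth, paths$truth)
  .write_resolved_config(config, "simulate")
  message("simulate: scenario=", config$scenario, " seed=", config$seed,
          " n=", graph$n, " -> ", config$out_dir)
  invisible(paths)
}

#' Fit stage: run the sampler and persist samples
#'
#' Reads the counts and adjacency written by [run_simulate] (or the files
#' named in the config), fits the shared-component model under the
#' configured hyperprior preset(s), writes long-format samples CSVs and a
#' fit log with DIC values.  With `preset = "both"` the two presets are
#' fitted and their DICs recorded for comparison.
#'
#' @param config A [run_config].
#' @return Invisibly, a list of `scsm_samples` objects keyed by preset.
#' @export
run_fit <- function(config) {
  graph <- .pipeline_graph(config)
  counts_path <- config$counts_file %||%
    file.path(config$out_dir, "counts.csv")
  table <- annualize_counts(read_counts(counts_path, graph))
  expected <- compute_expected(table)
  presets <- if (identical(config$preset, "both")) c("held", "ancelet")
             else config$preset
  mc <- do.call(mcmc_config, c(config$mcmc, list(seed = config$seed)))
  fits <- list()
  dics <- numeric(0)
  for (p in presets) {
    fit <- run_mcmc(mc, table, expected, prior_spec(p), graph)
    write_samples(fit, file.path(config$out_dir,
                                 paste0("samples_", p, ".csv")))
    d <- dic(fit, table, expected)
    dics[p] <- d$DIC
    fits[[p]] <- fit
    message("fit: preset=", p, " DIC=", round(d$DIC, 1),
            " (Dbar=", round(d$Dbar, 1), ", pD=", round(d$pD, 1), ")")
  }
  utils::write.csv(data.frame(preset = names(dics), DIC = unname(dics)),
                   file.path(config$out_dir, "dic.csv"), row.names = FALSE)
  .write_resolved_config(config, "fit")
  invisible(fits)
}

#' Summarize stage: posterior surfaces, shared summary, diagnostics
#'
#' Consumes a fitted `scsm_samples` object (or re-reads the persisted
#' samples of the first configured preset), writes `summary_areas.csv`,
#' `summary_shared.csv` and `diagnostics.csv` under `config$out_dir`, and
#' returns the three objects.  The diagnostics pass/fail flag is the
#' return value's `pass` element so callers (and the analysis drivers) can
#' exit nonzero on failure.
#'
#' @param config A [run_config].
#' @param fit Optional `scsm_samples`; otherwise read from disk.
#' @param table,expected Optional data (re-read/derived when omitted).
#' @return List with `areas` ([summarize_areas]), `shared`
#'   ([shared_summary]), `diagnostics` ([diagnostics_report]) and `pass`.
#' @export
run_summarize <- function(config, fit = NULL, table = NULL, expected = NULL) {
  graph <- .pipeline_graph(config)
  if (is.null(table)) {
    counts_path <- config$counts_file %||%
      file.path(config$out_dir, "counts.csv")
    table <- annualize_counts(read_counts(counts_path, graph))
  }
  if (is.null(expected)) expected <- compute_expected(table)
  if (is.null(fit)) {
    p <- if (identical(config$preset, "both")) "held" else config$preset
    fit <- read_samples(file.path(config$out_dir,
                                  paste0("samples_", p, ".csv")))
  }
  areas <- summarize_areas(fit, levels = config$levels)
  shared <- if (!isFALSE(fit$shared)) shared_summary(fit, config$levels)
  diag <- diagnostics_report(fit)
  utils::write.csv(areas, file.path(config$out_dir, "summary_areas.csv"),
                   row.names = FALSE)
  if (!is.null(shared)) {
    sh <- rbind(delta = shared$delta,
                risk_gradient_ratio = shared$risk_gradient_ratio,
                vf_outcome1 = shared$variance_fractions[1, ],
                vf_outcome2 = shared$variance_fractions[2, ])
    utils::write.csv(data.frame(quantity = rownames(sh), sh),
                     file.path(config$out_dir, "summary_shared.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(as.data.frame(diag),
                   file.path(config$out_dir, "diagnostics.csv"),
                   row.names = FALSE)
  .write_resolved_config(config, "summarize")
  message("summarize: diagnostics pass=", attr(diag, "pass"))
  list(areas = areas, shared = shared, diagnostics = diag,
       pass = attr(diag, "pass"))
}
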