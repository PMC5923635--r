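#' Gelman-Rubin potential scale reduction factor
#'
#' Variance-ratio PSRF from two or more chains of equal length `n`:
#' with `W` the mean within-chain variance and `B` the between-chain
#' variance (`n` times the variance of the chain means),
#' `PSRF = sqrt((W*(n-1)/n + B/n) / W)`.  Values near 1 indicate that the
#' chains have mixed over the same distribution.
#'
#' @param chains A list of equal-length numeric vectors (one per chain), or
#'   a draws-by-chains matrix.
#' @return The scalar PSRF.
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)),
                                          function(j) chains[, j])
  if (length(chains) < 2) stop("gelman_rubin needs at least two chains")
  len <- lengths(chains)
  if (length(unique(len)) != 1) stop("chains must have equal lengths")
  n <- len[1]
  if (n < 2) stop("chains too short (need >= 2 draws)")
  means <- vapply(chains, mean, numeric(1))
  W <- mean(vapply(chains, var, numeric(1)))
  B <- n * var(means)
  if (W == 0) return(if (B == 0) NA_real_ else Inf)
  sqrt((W * (n - 1) / n + B / n) / W)
}

#' Sample autocorrelation of a chain
#'
#' @param series Numeric vector.
#' @param max_lag Largest lag (must be below the series length).
#' @return Numeric vector of autocorrelations at lags `0..max_lag`
#'   (lag 0 is 1); all `NA` for a constant series.
#' @export
autocorrelation <- function(series, max_lag) {
  if (length(series) <= max_lag) stop("series shorter than max_lag")
  if (stats::sd(series) == 0) return(rep(NA_real_, max_lag + 1))
  as.vector(stats::acf(series, lag.max = max_lag, plot = FALSE,
                       demean = TRUE)$acf)
}

#' Batch-means Monte Carlo standard error
#'
#' The series is split into `n_batches` consecutive equal batches; the MC
#' standard error of the posterior mean is the standard deviation of the
#' batch means divided by `sqrt(n_batches)`.  Correlated draws inflate the
#' batch-mean spread, so this accounts (approximately) for autocorrelation.
#'
#' @param series Numeric vector; its length must be divisible by
#'   `n_batches`.
#' @param n_batches Number of batches (>= 2, default 50).
#' @return The Monte Carlo standard error.
#' @export
mc_error <- function(series, n_batches = 50) {
  stopifnot(n_batches >= 2)
  n <- length(series)
  if (n < 2 * n_batches || n %% n_batches != 0) {
    stop("series length ", n, " not divisible into ", n_batches,
         " batches of >= 2")
  }
  bm <- colMeans(matrix(series, nrow = n %/% n_batches))
  stats::sd(bm) / sqrt(n_batches)
}

#' Deviance information criterion
#'
#' `Dbar` is the posterior mean deviance over the kept draws; the plug-in
#' deviance `D(lambda-bar)` is evaluated at the posterior means of the
#' Poisson means `lambda[i,k]` (likelihood-level focus);
#' `pD = Dbar - D(lambda-bar)` and `DIC = Dbar + pD`.  Smaller DIC
#' indicates better fit.  A negative `pD` (a known DIC pathology under
#' poor convergence or strong non-normality) is flagged with a warning,
#' not an error.
#'
#' @param samples An `scsm_samples` object from [run_mcmc].
#' @param table,expected The data the samples were fitted to.
#' @return List with `Dbar`, `pD`, `DIC`.
#' @export
dic <- function(samples, table, expected) {
  dev <- pooled_draws(samples, "deviance")
  if (any(!is.finite(dev))) stop("non-finite deviance draw")
  Dbar <- mean(dev)
  lam_bar <- .posterior_mean_lambda(samples, expected)
  O <- cbind(table$O1, table$O2)
  Dhat <- -2 * sum(O * log(lam_bar) - lam_bar - lgamma(O + 1))
  pD <- Dbar - Dhat
  if (pD < 0) warning("negative pD (", signif(pD, 3), "): DIC unreliable")
  list(Dbar = Dbar, pD = pD, DIC = Dbar + pD)
}

.posterior_mean_lambda <- function(samples, expected) {
  n <- length(samples$area_ids)
  acc1 <- acc2 <- numeric(n)
  total <- 0L
  for (cc in samples$chains) {
    delta <- exp(cc$scalars[, "log_delta"])
    lp1 <- cc$scalars[, "alpha1"] + delta * cc$theta + cc$s1 + cc$u1
    lp2 <- cc$scalars[, "alpha2"] + cc$theta / delta + cc$s2 + cc$u2
    acc1 <- acc1 + colSums(exp(lp1))
    acc2 <- acc2 + colSums(exp(lp2))
    total <- total + nrow(cc$theta)
  }
  expected$e * cbind(acc1 / total, acc2 / total)
}

#' Convergence and precision report for a fitted model
#'
#' Computes, for each scalar parameter and for the deviance, the PSRF
#' across chains, the pooled posterior standard deviation, the batch-means
#' Monte Carlo error, and the lag-`acf_lags` autocorrelations; the latent
#' fields are summarized by the maximum PSRF over their elements.  The
#' Monte Carlo precision flag requires the MC error to be below 5% of the
#' posterior standard deviation (the standard monitoring criterion for
#' this model class); the convergence flag requires PSRF at or below
#' `psrf_limit`.
#'
#' @param samples An `scsm_samples` object with >= 2 chains.
#' @param psrf_limit Pass threshold for the PSRF (default 1.1).
#' @param n_batches Batches for [mc_error] (draw counts are truncated to a
#'   multiple of this).
#' @param acf_lags Lags reported for the autocorrelation columns.
#' @return An object of class `scsm_diagnostics`: a data frame with one row
#'   per monitored quantity (`psrf`, `post_sd`, `mc_err`, `mc_ratio`,
#'   `acf1`, `mc_ok`, `psrf_ok`), with attribute `pass` (all flags true).
#' @export
diagnostics_report <- function(samples, psrf_limit = 1.1, n_batches = 50,
                               acf_lags = 1) {
  if (length(samples$chains) < 2) {
    stop("diagnostics need at least two chains")
  }
  scalars <- colnames(samples$chains[[1]]$scalars)
  if (isFALSE(samples$shared)) {
    scalars <- setdiff(scalars, c("log_delta", "tau_theta"))
  }
  rows <- lapply(scalars, function(p) {
    per_chain <- lapply(samples$chains, function(cc) cc$scalars[, p])
    pooled <- unlist(per_chain, use.names = FALSE)
    nb <- min(n_batches, length(pooled) %/% 2)
    usable <- (length(pooled) %/% nb) * nb
    me <- mc_error(pooled[seq_len(usable)], nb)
    psd <- stats::sd(pooled)
    data.frame(parameter = p,
               psrf = if (stats::sd(pooled) == 0) NA_real_
                      else gelman_rubin(per_chain),
               post_sd = psd,
               mc_err = me,
               mc_ratio = if (psd > 0) me / psd else NA_real_,
               acf1 = autocorrelation(pooled, acf_lags)[acf_lags + 1],
               stringsAsFactors = FALSE)
  })
  fields <- c(if (!isFALSE(samples$shared)) "theta", "s1", "s2", "u1", "u2")
  frows <- lapply(fields, function(f) {
    n <- length(samples$area_ids)
    psrfs <- vapply(seq_len(n), function(j) {
      per_chain <- lapply(samples$chains, function(cc) cc[[f]][, j])
      if (stats::sd(unlist(per_chain)) == 0) NA_real_
      else gelman_rubin(per_chain)
    }, numeric(1))
    data.frame(parameter = paste0("max_psrf_", f),
               psrf = if (all(is.na(psrfs))) NA_real_
                      else max(psrfs, na.rm = TRUE),
               post_sd = NA_real_, mc_err = NA_real_, mc_ratio = NA_real_,
               acf1 = NA_real_, stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, c(rows, frows))
  rep$mc_ok <- is.na(rep$mc_ratio) | rep$mc_ratio < 0.05
  rep$psrf_ok <- is.na(rep$psrf) | rep$psrf <= psrf_limit
  structure(rep, pass = all(rep$mc_ok) && all(rep$psrf_ok),
            class = c("scsm_diagnostics", "data.frame"))
}

#' @export
print.scsm_diagnostics <- function(x, ...) {
  cat("Convergence diagnostics (pass:", attr(x, "pass"), ")\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
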