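#' Per-area posterior risk summaries
#'
#' For each area, the posterior median and credible interval of the two
#' relative risks (reconstructed per draw from the intercepts, scaling
#' parameter and fields), of the shared risk surface `exp(theta)`, the
#' exceedance probability `P(exp(theta) > 1)`, and a quantile-class label
#' of the shared-surface median for mapping.
#'
#' @param samples An `scsm_samples` object.
#' @param levels Credible-interval tail levels
#'   (default `c(0.025, 0.975)` for a 95% interval).
#' @param k Number of quantile classes for the map labels.
#' @return A data frame (class `scsm_summary`) with one row per area:
#'   `r1_med`, `r1_lo`, `r1_hi`, `r2_med`, `r2_lo`, `r2_hi`,
#'   `shared_med`, `shared_lo`, `shared_hi`, `exceedance`, `shared_class`.
#' @export
summarize_areas <- function(samples, levels = c(0.025, 0.975), k = 5) {
  stopifnot(length(levels) == 2, all(levels > 0 & levels < 1))
  if (!length(samples$chains) || !nrow(samples$chains[[1]]$theta)) {
    stop("empty samples")
  }
  r1 <- r2 <- ex <- NULL
  for (cc in samples$chains) {
    delta <- exp(cc$scalars[, "log_delta"])
    r1 <- rbind(r1, exp(cc$scalars[, "alpha1"] + delta * cc$theta +
                          cc$s1 + cc$u1))
    r2 <- rbind(r2, exp(cc$scalars[, "alpha2"] + cc$theta / delta +
                          cc$s2 + cc$u2))
    ex <- rbind(ex, exp(cc$theta))
  }
  q <- function(m) apply(m, 2, quantile, probs = c(0.5, levels), names = FALSE)
  q1 <- q(r1); q2 <- q(r2); qs <- q(ex)
  out <- data.frame(area_id = samples$area_ids,
                    r1_med = q1[1, ], r1_lo = q1[2, ], r1_hi = q1[3, ],
                    r2_med = q2[1, ], r2_lo = q2[2, ], r2_hi = q2[3, ],
                    shared_med = qs[1, ], shared_lo = qs[2, ],
                    shared_hi = qs[3, ],
                    exceedance = exceedance_probability(ex),
                    stringsAsFactors = FALSE)
  out$shared_class <- quantile_classes(out$shared_med,
                                       min(k, length(out$shared_med)))
  class(out) <- c("scsm_summary", "data.frame")
  out
}

#' Posterior exceedance probabilities
#'
#' Fraction of draws strictly greater than the threshold, per area --
#' the hotspot probability `P(risk > 1)` when applied to draws of a risk
#' surface.
#'
#' @param draws A draws-by-areas matrix (or a vector for one area).
#' @param threshold Exceedance threshold (default 1).
#' @return Per-area probabilities in `[0, 1]`.
#' @export
exceedance_probability <- function(draws, threshold = 1) {
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1)
  if (!nrow(draws)) stop("no draws")
  colMeans(draws > threshold)
}

#' Risk-gradient ratio of the scaling parameter
#'
#' The shared surface enters outcome 1 scaled by `delta` and outcome 2 by
#' `1/delta`, so the ratio of the two risk gradients is
#' `delta / (1/delta) = delta^2`.  Applied to posterior draws it returns a
#' median and credible interval; applied to a scalar it returns the point
#' value (e.g. a posterior median of 0.48 gives a ratio of about 0.23).
#'
#' @param delta Positive scalar or vector of posterior draws of the
#'   scaling parameter.
#' @param levels Credible-interval tail levels for the draws case.
#' @return For a scalar, `delta^2`; for draws, a named vector
#'   `c(median, lo, hi)` of `delta^2`.
#' @export
risk_gradient_ratio <- function(delta, levels = c(0.025, 0.975)) {
  stopifnot(all(delta > 0))
  r <- delta^2
  if (length(r) == 1) return(unname(r))
  setNames(quantile(r, c(0.5, levels), names = FALSE),
           c("median", "lo", "hi"))
}

#' Fraction of risk variation explained by the shared component
#'
#' Per draw, on the log-risk scale, the empirical variance across areas of
#' the shared contribution over the total:
#' `Var(delta*theta) / [Var(delta*theta) + Var(s1) + Var(u1)]` for
#' outcome 1, and with `theta/delta`, `s2`, `u2` for outcome 2; summarized
#' by the posterior median and credible interval.  Draws in which all
#' three contributions are constant across areas have an undefined
#' fraction and are returned as `NA` in the per-draw matrix (and dropped
#' from the summary).
#'
#' @param samples An `scsm_samples` object.
#' @param levels Credible-interval tail levels.
#' @return List with `summary` (2 x 3 matrix: outcome by median/lo/hi) and
#'   `draws` (per-draw fractions, one column per outcome).
#' @export
variance_fractions <- function(samples, levels = c(0.025, 0.975)) {
  rowvar <- function(m) {
    mu <- rowMeans(m)
    rowSums((m - mu)^2) / (ncol(m) - 1)
  }
  fr <- NULL
  for (cc in samples$chains) {
    delta <- exp(cc$scalars[, "log_delta"])
    v_sh1 <- rowvar(delta * cc$theta)
    v_sh2 <- rowvar(cc$theta / delta)
    tot1 <- v_sh1 + rowvar(cc$s1) + rowvar(cc$u1)
    tot2 <- v_sh2 + rowvar(cc$s2) + rowvar(cc$u2)
    f1 <- ifelse(tot1 > 0, v_sh1 / tot1, NA_real_)
    f2 <- ifelse(tot2 > 0, v_sh2 / tot2, NA_real_)
    fr <- rbind(fr, cbind(f1, f2))
  }
  colnames(fr) <- c("outcome1", "outcome2")
  sm <- t(apply(fr, 2, function(x)
    quantile(x, c(0.5, levels), names = FALSE, na.rm = TRUE)))
  colnames(sm) <- c("median", "lo", "hi")
  list(summary = sm, draws = fr)
}

#' Posterior summary of the shared-component scaling
#'
#' Median and credible interval of the scaling parameter `delta`, of the
#' risk-gradient ratio `delta^2`, and the per-outcome variance fractions.
#'
#' @param samples An `scsm_samples` object from a shared-component fit.
#' @param levels Credible-interval tail levels.
#' @return List (class `scsm_shared_summary`) with `delta`,
#'   `risk_gradient_ratio` (each `c(median, lo, hi)`) and
#'   `variance_fractions` (2 x 3 matrix).
#' @export
shared_summary <- function(samples, levels = c(0.025, 0.975)) {
  if (isFALSE(samples$shared)) {
    stop("samples come from the no-shared-component variant")
  }
  dd <- exp(pooled_draws(samples, "log_delta"))
  qd <- setNames(quantile(dd, c(0.5, levels), names = FALSE),
                 c("median", "lo", "hi"))
  structure(list(delta = qd,
                 risk_gradient_ratio = risk_gradient_ratio(dd, levels),
                 variance_fractions = variance_fractions(samples,
                                                         levels)$summary),
            class = "scsm_shared_summary")
}

#' @export
print.scsm_shared_summary <- function(x, ...) {
  f <- function(v) sprintf("%.3f (95%% CI %.3f, %.3f)", v[1], v[2], v[3])
  cat("Scaling parameter delta:", f(x$delta), "\n")
  cat("Risk-gradient ratio delta^2:", f(x$risk_gradient_ratio), "\n")
  cat("Variance fraction, outcome 1:", f(x$variance_fractions[1, ]), "\n")
  cat("Variance fraction, outcome 2:", f(x$variance_fractions[2, ]), "\n")
  invisible(x)
}

#' Equal-count quantile classes
#'
#' Assigns each value to one of `k` classes by sorted order, with class
#' sizes as equal as possible (sizes differ by at most one; the smaller
#' classes come last).  Ties are broken by position (area order), so the
#' labelling is deterministic.
#'
#' @param values Numeric vector of length `n >= k`.
#' @param k Number of classes (>= 2... well, >= 1; `k > n` is an error).
#' @return Integer class labels (1 = lowest values).
#' @export
quantile_classes <- function(values, k) {
  n <- length(values)
  if (k > n) stop("k (", k, ") exceeds number of values (", n, ")")
  if (k < 1) stop("k must be >= 1")
  if (length(unique(values)) == 1) return(rep(1L, n))
  ord <- order(values, seq_len(n))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  cls <- integer(n)
  cls[ord] <- rep(seq_len(k), sizes)
  cls
}
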