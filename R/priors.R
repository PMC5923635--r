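#' Prior specification for the shared-component model
#'
#' Two named presets mirror the hyperprior choices commonly used for
#' shared-component disease mapping:
#' \describe{
#'   \item{`"held"`}{Gamma(1.0, 0.01) (shape, rate) on all five precision
#'     parameters -- weakly informative, implied random-effect variance has
#'     its prior mode at 0.005 with infinite mean and variance;}
#'   \item{`"ancelet"`}{Gamma(0.1, 0.1) on the spatially structured
#'     precisions (shared and both specific surfaces) and
#'     Gamma(0.01, 0.01) on the two unstructured precisions.}
#' }
#' The intercepts get effectively flat Normal(0, sd = 1000) priors and the
#' log scaling parameter a Normal with mean 0 and precision 5.9, i.e. a
#' prior median of 1 for the scaling parameter and 95% prior probability
#' that the risk-gradient ratio lies between 1/5 and 5.
#'
#' @param preset `"held"` or `"ancelet"`.
#' @param alpha_sd Standard deviation of the (near-flat) intercept priors.
#' @param log_delta_mean,log_delta_precision Normal prior on the natural
#'   log of the scaling parameter.
#' @param tau_theta,tau_s1,tau_s2,tau_u1,tau_u2 Optional length-2
#'   `c(shape, rate)` overrides for individual precision hyperpriors.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(preset = c("held", "ancelet"),
                       alpha_sd = 1000,
                       log_delta_mean = 0,
                       log_delta_precision = 5.9,
                       tau_theta = NULL, tau_s1 = NULL, tau_s2 = NULL,
                       tau_u1 = NULL, tau_u2 = NULL) {
  preset <- match.arg(preset)
  base <- if (preset == "held") {
    list(tau_theta = c(1.0, 0.01), tau_s1 = c(1.0, 0.01),
         tau_s2 = c(1.0, 0.01), tau_u1 = c(1.0, 0.01), tau_u2 = c(1.0, 0.01))
  } else {
    list(tau_theta = c(0.1, 0.1), tau_s1 = c(0.1, 0.1), tau_s2 = c(0.1, 0.1),
         tau_u1 = c(0.01, 0.01), tau_u2 = c(0.01, 0.01))
  }
  for (nm in names(base)) {
    ov <- get(nm)
    if (!is.null(ov)) {
      stopifnot(length(ov) == 2, all(ov > 0))
      base[[nm]] <- as.numeric(ov)
    }
  }
  stopifnot(alpha_sd > 0, log_delta_precision > 0)
  structure(c(list(preset = preset, alpha_sd = alpha_sd,
                   log_delta_mean = log_delta_mean,
                   log_delta_precision = log_delta_precision),
              base),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("prior_spec (preset:", x$preset, ")\n")
  cat("  alpha ~ Normal(0,", x$alpha_sd, "^2); log delta ~ Normal(",
      x$log_delta_mean, ", precision", x$log_delta_precision, ")\n")
  for (nm in c("tau_theta", "tau_s1", "tau_s2", "tau_u1", "tau_u2")) {
    cat("  ", nm, " ~ Gamma(", x[[nm]][1], ", ", x[[nm]][2], ")\n", sep = "")
  }
  invisible(x)
}

#' Serialize / deserialize a prior specification
#'
#' @param priors A [prior_spec].
#' @param path File path; `.yaml`/`.yml` writes YAML, anything else JSON.
#' @return `read_prior_spec` returns a [prior_spec]; `write_prior_spec`
#'   returns `path` invisibly.
#' @export
write_prior_spec <- function(priors, path) {
  x <- unclass(priors)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_prior_spec
#' @export
read_prior_spec <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  prior_spec(preset = x$preset, alpha_sd = x$alpha_sd,
             log_delta_mean = x$log_delta_mean,
             log_delta_precision = x$log_delta_precision,
             tau_theta = x$tau_theta, tau_s1 = x$tau_s1, tau_s2 = x$tau_s2,
             tau_u1 = x$tau_u1, tau_u2 = x$tau_u2)
}
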