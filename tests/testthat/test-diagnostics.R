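test_that("the PSRF follows the between/within variance-ratio formula", {
  # hand oracle: chains {1,2,3} and {4,5,6}: n=3, W=1, B=13.5
  psrf <- gelman_rubin(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(psrf, sqrt((1 * 2 / 3 + 13.5 / 3) / 1), tolerance = 1e-12)

  # identical chains: B = 0, PSRF reduces to sqrt((n-1)/n) <= 1
  x <- rnorm(50)
  expect_lte(gelman_rubin(list(x, x)), 1)

  # long iid chains sit at 1
  set.seed(21)
  p <- gelman_rubin(list(rnorm(10000), rnorm(10000)))
  expect_gt(p, 0.99)
  expect_lt(p, 1.02)

  expect_error(gelman_rubin(list(rnorm(10))), "two chains")
  expect_error(gelman_rubin(list(rnorm(10), rnorm(9))), "equal lengths")
})

test_that("autocorrelations match their defining cases", {
  set.seed(22)
  x <- rnorm(200)
  a <- autocorrelation(x, 10)
  expect_equal(a[1], 1)
  expect_length(a, 11)

  alt <- rep(c(1, -1), 100)
  expect_lt(autocorrelation(alt, 1)[2], -0.98)

  # AR(1) with coefficient 0.8
  set.seed(23)
  ar <- as.vector(arima.sim(list(ar = 0.8), 50000))
  expect_gt(autocorrelation(ar, 1)[2], 0.78)
  expect_lt(autocorrelation(ar, 1)[2], 0.82)

  expect_true(all(is.na(autocorrelation(rep(1, 100), 3))))
  expect_error(autocorrelation(rnorm(5), 10), "shorter")
})

test_that("batch-means MC error matches the iid standard error", {
  set.seed(24)
  x <- rnorm(10000)
  me <- mc_error(x, 50)
  expect_lt(abs(me - 0.01), 0.005)   # theory: 1/sqrt(n) = 0.01
  expect_equal(mc_error(rep(3, 1000), 50), 0)
  # positively autocorrelated draws inflate the error
  dup <- rep(x[1:5000], each = 2)
  expect_gte(mc_error(dup, 50), 0.8 * me)
  expect_lte(mc_error(x, 50), sd(x))
  expect_error(mc_error(rnorm(30), 50), "batches")
})

test_that("DIC components follow their definitions on constructed samples", {
  # one area, five identical draws: pD = 0 and DIC = Dbar
  tab <- outcome_table("A", O1 = 4, O2 = 2, N = 100)
  ex <- list(e = cbind(e1 = 4, e2 = 2))
  mk <- function(ld_vec, th_vec) {
    sc <- cbind(alpha1 = 0 * ld_vec, alpha2 = 0 * ld_vec, log_delta = ld_vec,
                tau_theta = 1, tau_s1 = 1, tau_s2 = 1, tau_u1 = 1,
                tau_u2 = 1,
                deviance = vapply(seq_along(ld_vec), function(i) {
                  st <- model_state(log_delta = ld_vec[i],
                                    theta = th_vec[i])
                  deviance_scsm(st, tab, ex)
                }, numeric(1)))
    structure(list(chains = list(list(scalars = sc,
                                      theta = matrix(th_vec, ncol = 1),
                                      s1 = matrix(0, length(ld_vec), 1),
                                      s2 = matrix(0, length(ld_vec), 1),
                                      u1 = matrix(0, length(ld_vec), 1),
                                      u2 = matrix(0, length(ld_vec), 1))),
                   iterations = seq_along(ld_vec), shared = TRUE,
                   area_ids = "A"),
              class = "scsm_samples")
  }
  s_const <- mk(rep(0, 5), rep(0.1, 5))
  d <- dic(s_const, tab, ex)
  expect_equal(d$pD, 0, tolerance = 1e-10)
  expect_equal(d$DIC, d$Dbar, tolerance = 1e-10)

  # five distinct draws: arithmetic oracle for Dbar, pD, DIC
  th <- c(-0.2, -0.1, 0, 0.1, 0.2)
  s_var <- mk(rep(0, 5), th)
  lam1 <- 4 * exp(th); lam2 <- 2 * exp(th)
  devs <- -2 * (dpois(4, lam1, log = TRUE) + dpois(2, lam2, log = TRUE))
  Dbar <- mean(devs)
  lam_bar <- c(mean(lam1), mean(lam2))
  Dhat <- -2 * (dpois(4, lam_bar[1], log = TRUE) +
                  dpois(2, lam_bar[2], log = TRUE))
  d2 <- dic(s_var, tab, ex)
  expect_equal(d2$Dbar, Dbar, tolerance = 1e-10)
  expect_equal(d2$pD, Dbar - Dhat, tolerance = 1e-10)
  expect_equal(d2$DIC, 2 * Dbar - Dhat, tolerance = 1e-10)
})

test_that("the diagnostics report flags convergence and MC precision", {
  g <- grid_graph(4, 4, "queen")
  tab <- tiny_dataset(g, seed = 25)
  ex <- compute_expected(tab)
  fit <- run_mcmc(quick_config(seed = 26, iterations = 2100, burn_in = 600,
                               thinning = 3),
                  tab, ex, prior_spec("held"), g)
  rep <- diagnostics_report(fit)
  expect_s3_class(rep, "scsm_diagnostics")
  expect_true(all(c("psrf", "mc_ratio", "mc_ok", "psrf_ok") %in% names(rep)))
  expect_true(all(rep$psrf >= sqrt(1 / 2), na.rm = TRUE))
  expect_true(all(rep$mc_err <= rep$post_sd, na.rm = TRUE))
  expect_true(any(grepl("max_psrf_theta", rep$parameter)))
  expect_error(diagnostics_report(
    structure(list(chains = fit$chains[1]), class = "scsm_samples")),
    "two chains")
})
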