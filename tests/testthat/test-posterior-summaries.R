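test_that("area summaries reduce to the draws in degenerate cases", {
  mk_samples <- function(th, ld = 0) {
    nd <- nrow(th); n <- ncol(th)
    sc <- cbind(alpha1 = rep(0, nd), alpha2 = 0, log_delta = ld,
                tau_theta = 1, tau_s1 = 1, tau_s2 = 1, tau_u1 = 1,
                tau_u2 = 1, deviance = 0)
    z <- matrix(0, nd, n)
    structure(list(chains = list(list(scalars = sc, theta = th, s1 = z,
                                      s2 = z, u1 = z, u2 = z)),
                   iterations = seq_len(nd), shared = TRUE,
                   area_ids = paste0("a", seq_len(n))),
              class = "scsm_samples")
  }
  s1 <- mk_samples(matrix(c(0.1, -0.2), 1, 2))
  sm <- summarize_areas(s1, k = 2)
  expect_equal(sm$r1_med, exp(c(0.1, -0.2)))
  expect_equal(sm$shared_med, exp(c(0.1, -0.2)))
  expect_equal(sm$r1_lo, sm$r1_med, tolerance = 1e-12)

  szero <- mk_samples(matrix(0, 5, 3))
  smz <- summarize_areas(szero, k = 2)
  expect_equal(smz$shared_med, rep(1, 3))
  expect_equal(smz$shared_lo, rep(1, 3))
  expect_equal(smz$shared_hi, rep(1, 3))
  expect_true(all(smz$r1_med == 1))

  # medians match a sort-based quantile oracle on many draws
  set.seed(31)
  th <- matrix(rnorm(1000 * 2, 0, 0.4), 1000, 2)
  s <- mk_samples(th, ld = rep(log(0.5), 1000))
  sm2 <- summarize_areas(s)
  oracle_med <- apply(exp(0.5 * th), 2, function(x)
    quantile(x, 0.5, names = FALSE))
  expect_equal(sm2$r1_med, oracle_med, tolerance = 1e-12)
  expect_true(all(sm2$r1_lo <= sm2$r1_med & sm2$r1_med <= sm2$r1_hi))
  expect_error(summarize_areas(mk_samples(matrix(0, 0, 2))), "empty")
})

test_that("exceedance probabilities are draw fractions above the threshold", {
  expect_equal(exceedance_probability(matrix(2, 10, 1)), 1)
  # pairs (x, 2-x) are symmetric about 1
  x <- c(0.2, 0.7, 1.4, 1.8, 0.6, 1.3)
  expect_equal(unname(exceedance_probability(cbind(c(x, 2 - x)))), 0.5)
  # 17-draw counting oracle
  set.seed(32)
  d <- runif(17, 0.5, 1.5)
  expect_equal(unname(exceedance_probability(cbind(d))),
               sum(d > 1) / 17)
  expect_true(all(exceedance_probability(matrix(runif(50), 10, 5)) >= 0))
})

test_that("the risk-gradient ratio is the squared scaling parameter", {
  expect_equal(round(risk_gradient_ratio(0.48), 2), 0.23)
  expect_equal(risk_gradient_ratio(1), 1)
  expect_equal(risk_gradient_ratio(2), 4)
  # reciprocal symmetry
  for (d in c(0.3, 0.8, 1.7)) {
    expect_equal(risk_gradient_ratio(d) * risk_gradient_ratio(1 / d), 1)
  }
  set.seed(33)
  dd <- exp(rnorm(500, log(0.5), 0.1))
  r <- risk_gradient_ratio(dd)
  expect_named(r, c("median", "lo", "hi"))
  expect_equal(unname(r["median"]), quantile(dd^2, 0.5, names = FALSE))
})

test_that("variance fractions decompose the log-risk variance per draw", {
  nd <- 50; n <- 8
  set.seed(34)
  th <- matrix(rnorm(nd * n, 0, 0.5), nd, n)
  s1 <- matrix(rnorm(nd * n, 0, 0.2), nd, n)
  u1 <- matrix(rnorm(nd * n, 0, 0.1), nd, n)
  z <- matrix(0, nd, n)
  ld <- rnorm(nd, log(0.5), 0.05)
  sc <- cbind(alpha1 = rep(0, nd), alpha2 = 0, log_delta = ld,
              tau_theta = 1, tau_s1 = 1, tau_s2 = 1, tau_u1 = 1,
              tau_u2 = 1, deviance = 0)
  smp <- structure(list(chains = list(list(scalars = sc, theta = th,
                                           s1 = s1, s2 = z, u1 = u1,
                                           u2 = z)),
                        iterations = 1:nd, shared = TRUE,
                        area_ids = paste0("a", 1:n)),
                   class = "scsm_samples")
  vf <- variance_fractions(smp)
  # brute-force recomputation for a few draws
  for (i in c(1, 17, 50)) {
    d <- exp(ld[i])
    f1 <- var(d * th[i, ]) /
      (var(d * th[i, ]) + var(s1[i, ]) + var(u1[i, ]))
    expect_equal(vf$draws[i, "outcome1"], c(outcome1 = f1),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(vf$draws[i, "outcome2"], c(outcome2 = 1),
                 tolerance = 1e-12, ignore_attr = TRUE)  # s2 = u2 = 0
  }
  expect_true(all(vf$draws >= 0 & vf$draws <= 1, na.rm = TRUE))
  # all-zero contributions are undefined
  smp0 <- smp
  smp0$chains[[1]]$theta <- z
  smp0$chains[[1]]$s1 <- z
  smp0$chains[[1]]$u1 <- z
  vf0 <- variance_fractions(smp0)
  expect_true(all(is.na(vf0$draws[, "outcome1"])))
})

test_that("quantile classes are equal-count with deterministic tie-breaks", {
  expect_equal(quantile_classes(c(4, 1, 3, 2), 2), c(2L, 1L, 2L, 1L))
  expect_equal(quantile_classes(rep(7, 6), 3), rep(1L, 6))
  set.seed(35)
  cls <- quantile_classes(runif(140), 5)
  expect_equal(as.vector(table(cls)), rep(28L, 5))
  expect_error(quantile_classes(1:3, 4), "exceeds")
  # ties split by position
  expect_equal(quantile_classes(c(1, 1, 1, 5), 2), c(1L, 1L, 2L, 2L))
})
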