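test_that("relative risks follow the asymmetric shared-component form", {
  n <- 4
  st0 <- model_state(theta = numeric(n))
  expect_equal(unname(relative_risks(st0)), matrix(1, n, 2))

  # direct arithmetic: theta = 0.1, delta = 0.5
  st <- model_state(log_delta = log(0.5), theta = rep(0.1, n))
  r <- relative_risks(st)
  expect_equal(unname(r[, 1]), rep(exp(0.05), n))
  expect_equal(unname(r[, 2]), rep(exp(0.2), n))

  # at delta = 1 with no specific effects the outcomes coincide
  st1 <- model_state(log_delta = 0, theta = rnorm(n))
  r1 <- relative_risks(st1)
  expect_equal(r1[, 1], r1[, 2], ignore_attr = TRUE)

  # delta < 1 gives the steeper shared gradient to outcome 2
  set.seed(1)
  th <- rnorm(10)
  std <- model_state(log_delta = log(0.7), theta = th)
  rr <- log(relative_risks(std))
  expect_lt(var(rr[, 1]), var(rr[, 2]))
})

test_that("the Poisson log-likelihood matches a per-cell oracle", {
  tab <- outcome_table("A", O1 = 0, O2 = 0, N = 100)
  ex <- list(e = cbind(e1 = 1, e2 = 1))
  st <- model_state(theta = 0)
  # O = 0, lambda = 1 contributes -1 per cell
  expect_equal(log_likelihood(st, tab, ex), -2)

  # random table: brute-force per-cell summation with dpois
  g5 <- path_graph(5)
  tab5 <- tiny_dataset(g5, seed = 11)
  e5 <- compute_expected(tab5)
  set.seed(2)
  st5 <- model_state(alpha = c(0.1, -0.2), log_delta = log(0.8),
                     theta = rnorm(5, 0, 0.2), s1 = rnorm(5, 0, 0.1),
                     u2 = rnorm(5, 0, 0.1))
  lam <- e5$e * relative_risks(st5)
  oracle <- sum(dpois(tab5$O1, lam[, 1], log = TRUE)) +
    sum(dpois(tab5$O2, lam[, 2], log = TRUE))
  expect_equal(log_likelihood(st5, tab5, e5), oracle, tolerance = 1e-12)

  # doubling e with r halved leaves lambda and the likelihood unchanged
  e2x <- list(e = e5$e * 2)
  sth <- st5; sth$alpha <- st5$alpha - log(2)
  expect_equal(log_likelihood(sth, tab5, e2x),
               log_likelihood(st5, tab5, e5), tolerance = 1e-10)
})

test_that("ICAR pairwise density equals the Laplacian quadratic form", {
  g2 <- path_graph(2)
  # constant field: quadratic term vanishes
  expect_equal(icar_pairwise_log_density(c(3, 3), g2, tau = 2),
               (1 / 2) * log(2))
  # x = (0, 2), tau = 1: quadratic term -2
  expect_equal(icar_pairwise_log_density(c(0, 2), g2, tau = 1), -2)

  for (seed in 1:4) {
    g <- random_graph(5, p = 0.5, seed = seed)
    set.seed(seed + 100)
    x <- rnorm(5)
    tau <- runif(1, 0.5, 3)
    L <- dense_laplacian(g)
    oracle <- ((g$n - g$n_components) / 2) * log(tau) -
      (tau / 2) * drop(t(x) %*% L %*% x)
    expect_equal(icar_pairwise_log_density(x, g, tau), oracle,
                 tolerance = 1e-10)
    # exact translation invariance
    expect_identical(icar_pairwise_log_density(x + 5, g, tau),
                     icar_pairwise_log_density(x + 5, g, tau))
    expect_equal(icar_pairwise_log_density(x + 5, g, tau),
                 icar_pairwise_log_density(x, g, tau), tolerance = 1e-9)
  }
})

test_that("ICAR full conditionals are neighbour means with variance 1/(tau m)", {
  g2 <- path_graph(2)
  fc <- icar_full_conditional(1, c(0, 2), g2, tau = 4)
  expect_equal(fc$mean, 2)
  expect_equal(fc$variance, 1 / 4)

  g33 <- grid_graph(3, 3, "rook")
  x <- c(0, 1, 0, 2, 0, 3, 0, 4, 0)  # centre neighbours are 1,2,3,4
  fc5 <- icar_full_conditional(5, x, g33, tau = 2)
  expect_equal(fc5$mean, 2.5)
  expect_equal(fc5$variance, 1 / 8)

  # completing the square in the joint Laplacian form, random 5-node graph
  g <- random_graph(5, p = 0.6, seed = 3)
  set.seed(9)
  x <- rnorm(5)
  L <- dense_laplacian(g)
  for (i in which(g$m > 0)) {
    fc <- icar_full_conditional(i, x, g, tau = 1.7)
    expect_equal(fc$mean, -sum(L[i, -i] * x[-i]) / L[i, i],
                 tolerance = 1e-10)
    expect_equal(fc$variance, 1 / (1.7 * L[i, i]), tolerance = 1e-12)
  }
  gi <- suppressWarnings(areal_graph(c("A", "B", "C"), rbind(c("A", "B"))))
  expect_error(icar_full_conditional(3, c(0, 0, 0), gi, 1), "island")
})

test_that("the log-prior is the sum of its stated terms", {
  g <- path_graph(4)
  pr <- prior_spec("held")
  # mode of the log-delta prior at log(delta) = 0
  st0 <- model_state(theta = numeric(4))
  base <- log_prior(st0, pr, g)
  st_up <- st0; st_up$log_delta <- 0.5
  st_dn <- st0; st_dn$log_delta <- 1.0
  expect_lt(log_prior(st_up, pr, g), base)
  expect_lt(log_prior(st_dn, pr, g), log_prior(st_up, pr, g))

  set.seed(4)
  st <- model_state(alpha = rnorm(2), log_delta = rnorm(1, 0, 0.3),
                    theta = rnorm(4, 0, 0.5), s1 = rnorm(4, 0, 0.5),
                    s2 = rnorm(4, 0, 0.5), u1 = rnorm(4, 0, 0.5),
                    u2 = rnorm(4, 0, 0.5), tau_theta = 2, tau_s1 = 3,
                    tau_s2 = 4, tau_u1 = 5, tau_u2 = 6)
  oracle <- sum(dnorm(st$alpha, 0, pr$alpha_sd, log = TRUE)) +
    dnorm(st$log_delta, 0, 1 / sqrt(5.9), log = TRUE) +
    icar_pairwise_log_density(st$theta, g, st$tau_theta) +
    icar_pairwise_log_density(st$s1, g, st$tau_s1) +
    icar_pairwise_log_density(st$s2, g, st$tau_s2) +
    sum(dnorm(st$u1, 0, 1 / sqrt(st$tau_u1), log = TRUE)) +
    sum(dnorm(st$u2, 0, 1 / sqrt(st$tau_u2), log = TRUE)) +
    sum(dgamma(c(2, 3, 4, 5, 6), shape = 1, rate = 0.01, log = TRUE))
  expect_equal(log_prior(st, pr, g), oracle, tolerance = 1e-10)
})

test_that("the log-posterior composes and respects the identifiability shift", {
  g <- path_graph(6)
  tab <- tiny_dataset(g, seed = 5)
  ex <- compute_expected(tab)
  pr <- prior_spec("held")
  set.seed(6)
  st <- model_state(alpha = c(0.05, -0.05), log_delta = log(0.6),
                    theta = rnorm(6, 0, 0.3), s1 = rnorm(6, 0, 0.1),
                    u2 = rnorm(6, 0, 0.1))
  expect_equal(log_posterior(st, tab, ex, pr, g),
               log_likelihood(st, tab, ex) + log_prior(st, pr, g))

  # theta + c with alpha compensating leaves the posterior invariant
  # (ICAR translation-invariant; intercept priors flat at this scale)
  cshift <- 0.3
  delta <- exp(st$log_delta)
  st2 <- st
  st2$theta <- st$theta + cshift
  st2$alpha <- st$alpha - c(delta * cshift, cshift / delta)
  expect_equal(log_posterior(st2, tab, ex, pr, g),
               log_posterior(st, tab, ex, pr, g), tolerance = 1e-8)
})

test_that("prior presets serialize to YAML and JSON and read back", {
  pr <- prior_spec("ancelet")
  expect_equal(pr$tau_theta, c(0.1, 0.1))
  expect_equal(pr$tau_u1, c(0.01, 0.01))
  for (ext in c(".yaml", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    write_prior_spec(pr, f)
    back <- read_prior_spec(f)
    expect_equal(unclass(back), unclass(pr))
  }
  custom <- prior_spec("held", tau_u2 = c(0.5, 0.5))
  expect_equal(custom$tau_u2, c(0.5, 0.5))
  expect_equal(custom$tau_u1, c(1, 0.01))
})
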