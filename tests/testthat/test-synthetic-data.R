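test_that("ICAR fields are centred per component with the right contrasts", {
  g <- grid_graph(5, 4, "rook")
  set.seed(41)
  for (i in 1:5) {
    x <- sample_icar_field(g, tau = 2)
    expect_lt(abs(sum(x)), 1e-10)
  }
  # disconnected graph: each non-singleton component sums to zero,
  # singletons are exactly zero
  gd <- suppressWarnings(areal_graph(letters[1:5],
                                     rbind(c("a", "b"), c("c", "d"))))
  set.seed(42)
  xd <- sample_icar_field(gd, tau = 1)
  expect_lt(abs(sum(xd[1:2])), 1e-12)
  expect_lt(abs(sum(xd[3:4])), 1e-12)
  expect_identical(xd[5], 0)

  # 2-node path: the pairwise form exp(-tau/2 (x1-x2)^2), which is the
  # joint consistent with the conditional variance 1/(tau*m), makes the
  # contrast x1 - x2 Normal(0, 1/tau)
  g2 <- path_graph(2)
  set.seed(43)
  d <- replicate(20000, {
    x <- sample_icar_field(g2, tau = 1)
    x[1] - x[2]
  })
  se <- 1 * sqrt(2 / 20000)
  expect_lt(abs(var(d) - 1), 3 * se)

  # trace identity: mean pairwise energy = (n - c)/tau
  g3 <- grid_graph(4, 3, "rook")
  set.seed(44)
  en <- replicate(600, {
    x <- sample_icar_field(g3, tau = 3)
    sum((x[g3$edges[, 1]] - x[g3$edges[, 2]])^2)
  })
  target <- (g3$n - 1) / 3
  expect_lt(abs(mean(en) - target), 3 * sd(en) / sqrt(600))
})

test_that("populations are integer, bounded and reproducible", {
  p <- generate_populations(140, seed = 45)
  expect_true(all(p >= 7000 & p <= 10000))
  expect_true(all(p == round(p)))
  expect_identical(p, generate_populations(140, seed = 45))
  expect_equal(generate_populations(5, 8000, 8000, seed = 1),
               rep(8000L, 5))
})

test_that("the null scenario is Poisson around the expected counts", {
  g <- grid_graph(4, 5, "queen")
  set.seed(460)
  mean_spr <- replicate(200, {
    sim <- generate_dataset("null", g, seed = sample.int(1e6, 1))
    tab <- sim$table
    mean(standardized_prevalence_ratio(tab, compute_expected(tab)))
  })
  # SPRs under internal standardization are centred at 1 by construction;
  # their unweighted mean fluctuates by the Poisson noise only
  expect_lt(abs(mean(mean_spr) - 1),
            3 * sd(mean_spr) / sqrt(200) + 1e-3)
  # forward-then-standardize closure
  sim <- generate_dataset("null", g, seed = 46)
  e <- compute_expected(sim$table)
  expect_equal(colSums(e$e), c(e1 = sum(sim$table$O1),
                               e2 = sum(sim$table$O2)), tolerance = 1e-9)
})

test_that("a dominant shared surface induces correlated outcome maps", {
  g <- grid_graph(14, 10, "queen")
  set.seed(47)
  pos <- vapply(1:50, function(i) {
    sim <- generate_dataset("shared_dominant", g, seed = 5000 + i)
    spr <- standardized_prevalence_ratio(sim$table,
                                         compute_expected(sim$table))
    cor(log(pmax(spr[, 1], 1e-6)), log(pmax(spr[, 2], 1e-6))) > 0
  }, logical(1))
  expect_gte(mean(pos), 0.9)
})

test_that("generation is reproducible and obeys the scenario asymmetry", {
  g <- grid_graph(14, 10, "queen")
  a <- generate_dataset("shared_dominant", g, seed = 48)
  b <- generate_dataset("shared_dominant", g, seed = 48)
  expect_identical(a$table, b$table)
  expect_identical(a$truth$state$theta, b$truth$state$theta)

  # with delta = 0.5 the outcome-2 log-risk gradient is the steeper one
  st <- a$truth$state
  lr1 <- st$alpha[1] + 0.5 * st$theta + st$s1 + st$u1
  lr2 <- st$alpha[2] + 2.0 * st$theta + st$s2 + st$u2
  expect_lt(sd(lr1), sd(lr2))

  expect_error(generate_dataset("no_such_scenario", g), "arg")

  # the count floor regenerates sparse areas
  low <- scenario_params("custom", rates = c(0.002, 0.001))
  simf <- generate_dataset(low, grid_graph(3, 3, "rook"), seed = 49,
                           pop_range = c(3000, 4000), min_count = 5)
  expect_true(all(simf$table$O1 >= 5 & simf$table$O2 >= 5))
})

test_that("the truth sidecar serializes the generating state", {
  g <- grid_graph(3, 3, "rook")
  sim <- generate_dataset("discrepant", g, seed = 50)
  f <- withr::local_tempfile(fileext = ".json")
  write_truth(sim$truth, f)
  js <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(js$delta, 1)
  expect_equal(js$n, 9)
  expect_equal(js$theta, sim$truth$state$theta, tolerance = 1e-12)
  expect_equal(js$scenario, "discrepant")
})
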