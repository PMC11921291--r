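test_that("the design grid enumerates 54 scenarios with distinct seeds", {
  sc <- make_scenarios(replicates = 10L, base_seed = 71L)
  expect_identical(nrow(sc), 54L)
  expect_identical(anyDuplicated(sc[, c("beta", "rho", "tau2", "alpha")]), 0L)
  expect_setequal(unique(sc$beta), c(0, 0.4, 0.8))
  expect_setequal(unique(sc$rho), c(0, 0.4, 0.8))
  expect_setequal(unique(sc$tau2), c(0, 0.5, 1))
  expect_setequal(unique(sc$alpha), c(0, 0.25))
  expect_true(all(sc$n_studies == 20L))
  expect_identical(anyDuplicated(sc$seed), 0L)
  # reproducible from the base seed
  sc2 <- make_scenarios(replicates = 10L, base_seed = 71L)
  expect_identical(sc$seed, sc2$seed)
  expect_false(identical(sc$seed, make_scenarios(10L, base_seed = 72L)$seed))
})

test_that("the variance grid runs 0.05 to 1.00 in steps of 0.05", {
  v <- variance_grid()
  expect_length(v, 20L)
  expect_equal(v, seq(0.05, 1, by = 0.05))
})

test_that("simulated data honour the generating moments", {
  # tau2 = 0, rho = 0, beta = 0: theta_hat_i ~ N(alpha, sigma_i^2)
  sc <- toy_scenario(alpha = 0.25, beta = 0, tau2 = 0, rho = 0, seed = 73L)
  R <- 1000
  th <- matrix(NA_real_, R, 20)
  gh <- matrix(NA_real_, R, 20)
  gm <- matrix(NA_real_, R, 20)
  for (r in seq_len(R)) {
    sim <- simulate_dataset(sc, r)
    th[r, ] <- sim$table$theta_hat
    gh[r, ] <- sim$table$gamma_hat
    gm[r, ] <- sim$truth$gammas
  }
  s2 <- variance_grid()
  for (i in c(1L, 10L, 20L)) {
    expect_lt(abs(mean(th[, i]) - 0.25), 3 * sqrt(s2[i] / R))
    # variance of a variance estimate: 2 sigma^4 / (R - 1)
    expect_lt(abs(var(th[, i]) - s2[i]), 3 * sqrt(2 * s2[i]^2 / (R - 1)))
    # gamma_hat variance = Var U(-5, 5) + delta_i^2 = 25/3 + delta_i^2
    v_target <- 25 / 3 + s2[i]
    expect_equal(var(gh[, i]), v_target, tolerance = 0.15)
  }
})

test_that("within-study correlation is reproduced by the residual pairs", {
  sc <- toy_scenario(alpha = 0, beta = 0.4, tau2 = 0, rho = 0.8, seed = 74L)
  R <- 1500
  e_th <- matrix(NA_real_, R, 20)
  e_gh <- matrix(NA_real_, R, 20)
  for (r in seq_len(R)) {
    sim <- simulate_dataset(sc, r)
    e_th[r, ] <- sim$table$theta_hat - 0 - 0.4 * sim$truth$gammas
    e_gh[r, ] <- sim$table$gamma_hat - sim$truth$gammas
  }
  for (i in c(3L, 12L)) {
    expect_equal(cor(e_th[, i], e_gh[, i]), 0.8, tolerance = 0.05)
  }
})

test_that("fixed gammas are held across replicates when requested", {
  sc <- toy_scenario(seed = 75L)
  g0 <- rep(c(-2, 2), 10)
  s1 <- simulate_dataset(sc, 1L, fixed_gammas = g0)
  s2 <- simulate_dataset(sc, 2L, fixed_gammas = g0)
  expect_identical(s1$truth$gammas, g0)
  expect_identical(s2$truth$gammas, g0)
  expect_false(identical(s1$table$gamma_hat, s2$table$gamma_hat))
})

test_that("method evaluation records estimates, coverage and convergence", {
  sc <- toy_scenario(alpha = 0, beta = 0.4, tau2 = 0, rho = 0.4, seed = 76L)
  sim <- simulate_dataset(sc, 1L)
  ev <- evaluate_methods(sim$table, sim$truth, methods = c("mle", "adjusted"))
  expect_identical(nrow(ev), 2L)
  expect_true(all(ev$converged))
  expect_true(all(ev$tau2 >= 0))
  expect_true(all(ev$method %in% c("mle", "adjusted")))
})

test_that("matched gradients leave the two frequentist tau2 estimates close", {
  # beta = rho (with sigma = delta) makes every b_i approximately 0, so the
  # adjustment should barely move tau2
  sc <- toy_scenario(alpha = 0, beta = 0.4, tau2 = 0.5, rho = 0.4, seed = 77L)
  diffs <- vapply(1:20, function(r) {
    sim <- simulate_dataset(sc, r)
    ev <- evaluate_methods(sim$table, sim$truth)
    abs(ev$tau2[ev$method == "adjusted"] - ev$tau2[ev$method == "mle"])
  }, numeric(1))
  expect_lt(mean(diffs), 0.1)
})

test_that("summaries reduce to the textbook formulas", {
  raw <- data.frame(method = "mle",
                    alpha = c(0.3, 0.3, 0.3), beta = c(1, 2, 3),
                    tau2 = c(0.5, 0.5, 0.5), tau2_median = NA_real_,
                    cover_alpha = c(TRUE, TRUE, TRUE),
                    cover_beta = c(TRUE, FALSE, TRUE),
                    converged = TRUE, replicate = 1:3,
                    scenario_id = 1L, true_beta = 2, true_rho = 0,
                    true_tau2 = 1, true_alpha = 0)
  s <- summarize_simulation(raw)
  a <- s[s$parameter == "alpha", ]
  expect_equal(a$bias, 0.3)           # constant estimator: constant - truth
  expect_equal(a$coverage, 1)         # all-hit indicator
  b <- s[s$parameter == "beta", ]
  expect_equal(b$bias, 0)
  expect_equal(b$coverage, 2 / 3)
  expect_equal(b$mc_se_coverage, sqrt((2 / 3) * (1 / 3) / 3))
  t2 <- s[s$parameter == "tau2", ]
  expect_equal(t2$bias, -0.5)
  expect_true(is.na(t2$coverage))
  expect_identical(unique(s$n_converged), 3L)
})

test_that("run_simulation stitches scenarios and replicates together", {
  sc <- make_scenarios(replicates = 3L, base_seed = 78L)
  sub <- sc[sc$beta == 0.8 & sc$rho == 0 & sc$tau2 == 1 & sc$alpha == 0, ]
  raw <- run_simulation(sub, methods = "mle")
  expect_identical(nrow(raw), 3L)
  expect_true(all(raw$converged))
  s <- summarize_simulation(raw)
  expect_identical(nrow(s), 3L)  # one per parameter
})
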