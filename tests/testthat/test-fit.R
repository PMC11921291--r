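test_that("maximum likelihood fits are certified by the estimating equations", {
  sc <- toy_scenario(alpha = 0, beta = 0.8, tau2 = 1, rho = 0, seed = 51L)
  for (r in 1:5) {
    sim <- simulate_dataset(sc, r)
    fit <- fit_mle(sim$table)
    expect_true(fit$converged)
    expect_lt(fit$ee_max_abs, 1e-6)
    # Wald intervals contain their point estimates
    expect_true(fit$ci$alpha[1] <= fit$alpha && fit$alpha <= fit$ci$alpha[2])
    expect_true(fit$ci$beta[1] <= fit$beta && fit$beta <= fit$ci$beta[2])
  }
})

test_that("fewer than three studies is under-identified", {
  tab <- study_table(c(0, 1), c(1, 1), c(0, 1), c(1, 1), 0)
  expect_error(fit_mle(tab), "under-identified")
})

test_that("bias terms follow the closed form and its cross-check", {
  # beta equal to the within-study gradient kills the adjustment
  tab <- study_table(0.5, se_theta = 0.6, gamma_hat = 0.1, se_gamma = 0.3,
                     rho = 0.4)
  beta_match <- 0.4 * 0.6 / 0.3
  expect_equal(bias_terms(tab, beta_match, 0.5), 0)

  # unit-variance case: b = 1 / (1 + 0 + 1)
  tab2 <- study_table(0, 1, 0, 1, 0)
  expect_equal(bias_terms(tab2, 1, 0), 0.5)

  # cross-check against (beta - rho sigma / delta) * w1 with w1 from the
  # explicit adjoint formula, over many random draws
  set.seed(52)
  worst <- 0
  for (k in 1:200) {
    n <- 50L
    tab3 <- random_table(n)
    beta <- rnorm(1); tau2 <- runif(1, 0, 2)
    b_direct <- bias_terms(tab3, beta, tau2)
    dq <- derive_quantities(tab3, param_state(0, beta, tau2, rep(0, n)))
    b_w1 <- (beta - dq$within_gradient) * dq$w1
    worst <- max(worst, max(abs(b_direct - b_w1)))
    expect_true(all(b_direct >= 0 & b_direct < 1))
  }
  expect_lt(worst, 1e-12)
})

test_that("adjusted tau2 update dominates the unadjusted one", {
  # all b = 0 reproduces the unadjusted update exactly
  gam <- c(-1, 0, 1)
  tab <- study_table(c(0.3, -0.2, 0.6), rep(0.8, 3), gam, rep(0.8, 3), 0.5)
  beta0 <- 0.5  # equals rho sigma / delta since sigma = delta
  p0 <- param_state(0.1, beta0, 0.4, gammas = gam)
  expect_equal(bias_terms(tab, beta0, 0.4), rep(0, 3))
  expect_equal(tau2_adjusted_update(tab, p0)$raw, tau2_update(tab, p0)$raw,
               tolerance = 1e-12)

  # single study with b = 0.5, v2 = 1: raw = 4 r^2 - 1
  tab1 <- study_table(1.3, 1, 0.2, 1, 0)
  p1 <- param_state(0, 1, 0, gammas = 0.5)
  r2 <- (1.3 - 0.5)^2
  expect_equal(tau2_adjusted_update(tab1, p1)$raw, 4 * r2 - 1,
               tolerance = 1e-12)

  # inflation property over random inputs
  set.seed(53)
  for (k in 1:100) {
    n <- sample(3:10, 1)
    tabk <- random_table(n)
    pk <- random_params(n)
    expect_gte(tau2_adjusted_update(tabk, pk)$raw, tau2_update(tabk, pk)$raw)
  }
})

test_that("adjusted fit reaches a certified joint fixed point", {
  sc <- toy_scenario(alpha = 0.25, beta = 0.8, tau2 = 0.5, rho = 0.4,
                     seed = 54L)
  sim <- simulate_dataset(sc, 1L)
  fit <- fit_adjusted(sim$table)
  expect_true(fit$converged)
  expect_lt(fit$ee_max_abs, 1e-6)
  expect_true(all(fit$bias_terms >= 0 & fit$bias_terms < 1))
  # adjusted tau2 never below the MLE tau2 for the same data
  mle <- fit_mle(sim$table)
  expect_gte(fit$tau2, mle$tau2 - 1e-8)
})

test_that("adjusted and MLE fits coincide when all bias terms vanish", {
  # fixture emulating a small PFS/OS review where the within-study
  # gradients bracket the fitted slope: both methods truncate tau2 to zero
  tab <- make_fixture("example1_like", seed = 7L)
  mle <- fit_mle(tab)
  adj <- fit_adjusted(tab)
  expect_equal(adj$tau2, mle$tau2)
  expect_equal(adj$alpha, mle$alpha, tolerance = 1e-6)
  expect_equal(adj$beta, mle$beta, tolerance = 1e-6)
})

test_that("single-pass adjusted mode runs and reports a constrained fit", {
  sc <- toy_scenario(alpha = 0, beta = 0, tau2 = 1, rho = 0.8, seed = 55L)
  sim <- simulate_dataset(sc, 1L)
  one <- fit_adjusted(sim$table, mode = "single_pass")
  expect_s3_class(one, "dh_fit")
  expect_true(is.finite(one$tau2))
  expect_gte(one$tau2, 0)
})

test_that("Wald intervals use the exact normal quantile", {
  expect_equal(unname(wald_interval(0, 1, 0.95)),
               c(-1.959964, 1.959964), tolerance = 1e-6)
  tiny <- wald_interval(0.3, 1, 1e-12)
  expect_equal(unname(tiny), c(0.3, 0.3), tolerance = 1e-6)
  expect_error(wald_interval(0, 1, 1.2))
})

test_that("standard errors recover the known-variance regression closed form", {
  # gammas pinned by tiny se_gamma and tau2 known: the theta-part is plain
  # linear regression with unit error SD; with centered gammas the alpha
  # coordinate is orthogonal to beta, so SE(alpha) = sigma / sqrt(n)
  gam <- c(-2, -1, 0, 1, 2)
  theta <- 0.5 + 0.3 * gam
  tab <- study_table(theta, rep(1, 5), gam, rep(1e-6, 5), 0)
  p <- param_state(0.5, 0.3, 0, gammas = gam)
  se <- standard_errors(tab, p, tau2_known = TRUE)
  expect_equal(se$alpha, 1 / sqrt(5), tolerance = 1e-4)
  expect_equal(se$beta, 1 / sqrt(sum(gam^2)), tolerance = 1e-4)
})

test_that("fitted standard errors are calibrated against replicate spread", {
  # larger table (n = 50) with matched gradients, where the problem is
  # regular and the asymptotic SEs should track the sampling spread
  sim_50 <- function(seed) {
    set.seed(seed)
    n <- 50L
    sigma <- sqrt(rep(seq(0.05, 1, 0.05), length.out = n))
    rho <- 0.8
    gam <- runif(n, -5, 5)
    gh <- gam + sigma * rnorm(n)
    v2 <- sigma^2 * (1 - rho^2)
    th <- 0.8 * gam + rho * (gh - gam) + sqrt(v2 + 0.5) * rnorm(n)
    study_table(th, sigma, gh, sigma, rho)
  }
  R <- 400
  out <- t(vapply(seq_len(R), function(r) {
    f <- fit_mle(sim_50(1000L + r))
    c(f$beta, f$se$beta)
  }, numeric(2)))
  ratio <- mean(out[, 2]) / sd(out[, 1])
  expect_lt(abs(ratio - 1), 0.10)
})

test_that("model-based gammas shrink squared residuals by exactly (1 - b)", {
  # the incidental-parameter effect in closed form: replacing the true
  # gamma_i by its model-based estimate multiplies the expected squared
  # residual by (1 - b_i); the adjusted update inflates residuals to undo
  # this shrinkage
  set.seed(57)
  sigma <- 1; delta <- 1.2; rho <- -0.5; beta <- 0.3; tau2 <- 0.9; alpha <- 0.2
  g <- rho * sigma / delta
  v2 <- sigma^2 * (1 - rho^2)
  R <- 200000L
  gam <- runif(R, -5, 5)
  gh <- gam + delta * rnorm(R)
  th <- alpha + beta * gam + g * (gh - gam) + sqrt(v2 + tau2) * rnorm(R)
  big <- study_table(th, rep(sigma, R), gh, rep(delta, R), rho,
                     label = seq_len(R))
  gmle <- gamma_update(big, alpha, beta, tau2)
  mu <- alpha + beta * gmle + g * (gh - gmle)
  b <- bias_terms(big, beta, tau2)[1L]
  ratio <- mean((th - mu)^2) / (v2 + tau2)
  mc_se <- sd((th - mu)^2) / sqrt(R) / (v2 + tau2)
  expect_lt(abs(ratio - (1 - b)), 4 * mc_se)
})
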