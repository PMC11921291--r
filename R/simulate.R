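#' Enumerate the simulation design grid
#'
#' The full factorial grid of the bias/coverage study: n = 20 studies, true
#' gamma_i ~ U(-5, 5), per-study within-study variances
#' sigma_i^2 = delta_i^2 = 0.05, 0.10, ..., 1.00 (one value per study,
#' fixed across replicates), beta in {0, 0.4, 0.8}, shared rho in
#' {0, 0.4, 0.8}, tau2 in {0, 0.5, 1}, alpha in {0, 0.25}:
#' 3 x 3 x 3 x 2 = 54 scenarios.
#'
#' @param replicates replicates per scenario (1000 at full scale).
#' @param base_seed master integer seed; every scenario receives a distinct
#'   derived seed and every (scenario, replicate) pair a distinct child
#'   seed, so any single replicate is reproducible in isolation.
#' @return data.frame of class `"sim_scenarios"`, one row per scenario, with
#'   columns `scenario_id`, `beta`, `rho`, `tau2`, `alpha`, `n_studies`,
#'   `replicates`, `seed`.
#' @export
make_scenarios <- function(replicates = 1000L, base_seed = 1L) {
  stopifnot(replicates >= 1)
  grid <- expand.grid(beta = c(0, 0.4, 0.8), rho = c(0, 0.4, 0.8),
                      tau2 = c(0, 0.5, 1), alpha = c(0, 0.25),
                      KEEP.OUT.ATTRS = FALSE)
  grid$scenario_id <- seq_len(nrow(grid))
  grid$n_studies <- 20L
  grid$replicates <- as.integer(replicates)
  grid$seed <- derive_seed(base_seed, grid$scenario_id, 0L)
  grid <- grid[, c("scenario_id", "beta", "rho", "tau2", "alpha",
                   "n_studies", "replicates", "seed")]
  class(grid) <- c("sim_scenarios", "data.frame")
  grid
}

# Counter-based child seeds: mixes (base, scenario, replicate) through a
# Weyl/multiplicative hash, kept inside the 32-bit signed range.
derive_seed <- function(base_seed, scenario_id, replicate) {
  x <- (as.double(base_seed) %% 2147483647) * 2654435761 +
    as.double(scenario_id) * 40503 + as.double(replicate) * 69621
  as.integer(x %% 2147483647)
}

#' Per-study within-study variance grid
#'
#' The 20 values 0.05, 0.10, ..., 1.00 assigned to studies 1..20 (study i
#' gets 0.05 * i); used as both sigma_i^2 and delta_i^2.
#' @return numeric vector of length 20.
#' @export
variance_grid <- function() seq(0.05, 1, by = 0.05)

#' Simulate one dataset from a scenario
#'
#' Draws gamma_i ~ U(-5, 5) independently (fresh each replicate unless
#' `fixed_gammas` is supplied), then `(theta_hat_i, gamma_hat_i)` from the
#' marginal bivariate normal model with the scenario's alpha, beta, tau2,
#' shared rho and per-study variances.
#'
#' @param scenario one row of a [make_scenarios()] data.frame (or any list
#'   with fields `alpha`, `beta`, `tau2`, `rho`, `n_studies`, `seed`,
#'   `scenario_id`).
#' @param replicate_index replicate counter, used to derive the child seed.
#' @param fixed_gammas optional vector of true gamma values to hold fixed
#'   across replicates (sensitivity option); default redraws them.
#' @return list with `table` (a `study_table`) and `truth` (a
#'   `param_state` holding the generating parameter values).
#' @export
simulate_dataset <- function(scenario, replicate_index = 1L,
                             fixed_gammas = NULL) {
  n <- scenario$n_studies %||% 20L
  set.seed(derive_seed(scenario$seed %||% 1L,
                       scenario$scenario_id %||% 0L, replicate_index))
  s2 <- variance_grid()[seq_len(n)]
  sigma <- sqrt(s2); delta <- sigma  # sigma_i^2 = delta_i^2 by design
  rho <- scenario$rho
  gammas <- fixed_gammas %||% stats::runif(n, -5, 5)
  gamma_hat <- gammas + delta * stats::rnorm(n)
  # conditional draw given gamma_hat: mean has the within-study gradient,
  # variance v^2 + tau2
  v2 <- s2 * (1 - rho^2)
  theta_hat <- scenario$alpha + scenario$beta * gammas +
    (rho * sigma / delta) * (gamma_hat - gammas) +
    sqrt(v2 + scenario$tau2) * stats::rnorm(n)
  list(table = study_table(theta_hat, sigma, gamma_hat, delta, rho),
       truth = param_state(scenario$alpha, scenario$beta, scenario$tau2,
                           gammas))
}

#' Apply estimation methods to one simulated dataset
#'
#' Runs each requested method and records point estimates of alpha, beta and
#' tau2 (posterior mean and median for the Bayesian method), indicators that
#' the nominal 95% interval for alpha and beta covered the truth, and a
#' convergence flag. A failed fit is recorded as non-converged, never
#' propagated as an error.
#'
#' @param tab a `study_table`.
#' @param truth the generating `param_state`.
#' @param methods subset of `c("mle", "adjusted", "bayes")`.
#' @param fit_opts a [fit_options()] list for the frequentist methods.
#' @param mcmc_opts an [mcmc_options()] list for the Bayesian method.
#' @return data.frame with one row per method.
#' @export
evaluate_methods <- function(tab, truth, methods = c("mle", "adjusted"),
                             fit_opts = fit_options(),
                             mcmc_opts = mcmc_options(burn_in = 500L,
                                                      kept_iterations = 2000L)) {
  stopifnot(all(methods %in% c("mle", "adjusted", "bayes")))
  rows <- lapply(methods, function(m) {
    base <- data.frame(method = m, alpha = NA_real_, beta = NA_real_,
                       tau2 = NA_real_, tau2_median = NA_real_,
                       cover_alpha = NA, cover_beta = NA, converged = FALSE)
    res <- tryCatch(suppressWarnings({
      if (m == "bayes") {
        bf <- fit_bayes(tab, mcmc_opts)
        s <- bf$summary
        get <- function(p, col) s[s$parameter == p, col]
        data.frame(method = m,
                   alpha = get("alpha", "mean"), beta = get("beta", "mean"),
                   tau2 = get("tau2", "mean"),
                   tau2_median = get("tau2", "median"),
                   cover_alpha = get("alpha", "pct_lower") <= truth$alpha &
                     truth$alpha <= get("alpha", "pct_upper"),
                   cover_beta = get("beta", "pct_lower") <= truth$beta &
                     truth$beta <= get("beta", "pct_upper"),
                   converged = TRUE)
      } else {
        f <- if (m == "mle") fit_mle(tab, fit_opts) else fit_adjusted(tab, fit_opts)
        data.frame(method = m, alpha = f$alpha, beta = f$beta, tau2 = f$tau2,
                   tau2_median = NA_real_,
                   cover_alpha = f$ci$alpha[1L] <= truth$alpha &
                     truth$alpha <= f$ci$alpha[2L],
                   cover_beta = f$ci$beta[1L] <= truth$beta &
                     truth$beta <= f$ci$beta[2L],
                   converged = f$converged)
      }
    }), error = function(e) base)
    res
  })
  do.call(rbind, rows)
}

#' Run replicates for a set of scenarios
#'
#' @param scenarios a [make_scenarios()] data.frame (possibly filtered).
#' @param methods methods passed to [evaluate_methods()].
#' @param fit_opts,mcmc_opts method options.
#' @return data.frame of raw per-replicate results with scenario
#'   descriptors attached.
#' @export
run_simulation <- function(scenarios, methods = c("mle", "adjusted"),
                           fit_opts = fit_options(),
                           mcmc_opts = mcmc_options(burn_in = 500L,
                                                    kept_iterations = 2000L)) {
  out <- vector("list", nrow(scenarios))
  for (i in seq_len(nrow(scenarios))) {
    sc <- scenarios[i, ]
    reps <- lapply(seq_len(sc$replicates), function(r) {
      sim <- simulate_dataset(sc, r)
      ev <- evaluate_methods(sim$table, sim$truth, methods, fit_opts, mcmc_opts)
      ev$replicate <- r
      ev
    })
    block <- do.call(rbind, reps)
    for (col in c("scenario_id", "beta", "rho", "tau2", "alpha")) {
      block[[paste0("true_", col)]] <- sc[[col]]
    }
    names(block)[names(block) == "true_scenario_id"] <- "scenario_id"
    out[[i]] <- block
  }
  do.call(rbind, out)
}

#' Summarize raw simulation results into bias and coverage
#'
#' Per scenario x method x parameter: mean bias (estimate minus truth),
#' empirical coverage of the nominal-95% intervals for alpha and beta, and
#' Monte-Carlo standard errors (SD/sqrt(R) for bias, binomial
#' sqrt(p(1-p)/R) for coverage). Non-converged replicates are counted and
#' excluded.
#'
#' @param raw output of [run_simulation()].
#' @return data.frame, one row per scenario x method x parameter, with
#'   columns `bias`, `coverage`, `mc_se_bias`, `mc_se_coverage`,
#'   `n_converged`, `n_failed`.
#' @export
summarize_simulation <- function(raw) {
  stopifnot(nrow(raw) >= 1)
  keys <- unique(raw[, c("scenario_id", "true_beta", "true_rho",
                         "true_tau2", "true_alpha", "method")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sel <- raw$scenario_id == k$scenario_id & raw$method == k$method
    block <- raw[sel, ]
    ok <- block[block$converged %in% TRUE, ]
    n_fail <- nrow(block) - nrow(ok)
    per_param <- lapply(c("alpha", "beta", "tau2"), function(p) {
      truth <- k[[paste0("true_", p)]]
      est <- ok[[p]]
      R <- length(est)
      cov <- if (p == "tau2") NA_real_ else mean(ok[[paste0("cover_", p)]])
      data.frame(k, parameter = p,
                 bias = mean(est) - truth,
                 mc_se_bias = stats::sd(est) / sqrt(max(R, 1L)),
                 coverage = cov,
                 mc_se_coverage = if (is.na(cov)) NA_real_ else
                   sqrt(cov * (1 - cov) / R),
                 n_converged = R, n_failed = n_fail,
                 row.names = NULL)
    })
    do.call(rbind, per_param)
  })
  do.call(rbind, rows)
}
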