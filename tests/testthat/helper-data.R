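# Shared generators for random test inputs. All tests that use randomness
# set their own seed first.

random_table <- function(n, rho_range = c(-0.9, 0.9)) {
  study_table(theta_hat = rnorm(n, 0, 1),
              se_theta = runif(n, 0.2, 1),
              gamma_hat = rnorm(n, 0, 2),
              se_gamma = runif(n, 0.2, 1),
              rho = runif(n, rho_range[1L], rho_range[2L]))
}

random_params <- function(n, tau2_max = 2) {
  param_state(alpha = rnorm(1), beta = rnorm(1),
              tau2 = runif(1, 0, tau2_max), gammas = rnorm(n, 0, 2))
}

# A small scenario row usable by simulate_dataset() without the full grid.
toy_scenario <- function(alpha = 0, beta = 0.8, tau2 = 1, rho = 0,
                         n = 20L, seed = 1L, id = 1L) {
  list(alpha = alpha, beta = beta, tau2 = tau2, rho = rho,
       n_studies = n, seed = seed, scenario_id = id)
}
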