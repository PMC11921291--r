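#' Marginal log-likelihood of the Daniels-Hughes model
#'
#' Sum over studies of the bivariate-normal log density of
#' `(theta_hat_i, gamma_hat_i)` with mean `(alpha + beta gamma_i, gamma_i)`
#' and covariance
#' `[[sigma_i^2 + tau2, rho_i sigma_i delta_i], [rho_i sigma_i delta_i, delta_i^2]]`.
#' Each study's 2x2 density is evaluated in closed form via the adjoint
#' inverse, so no generic matrix inversion is performed.
#'
#' @param tab a `study_table`.
#' @param params a `param_state` with `tau2 >= 0`.
#' @return scalar log-likelihood.
#' @seealso [loglik_factorized()] for the algebraically identical
#'   marginal-times-conditional form used as an internal cross-check.
#' @export
loglik_marginal <- function(tab, params) {
  check_alignment(tab, params)
  s2 <- tab$se_theta^2 + params$tau2
  d2 <- tab$se_gamma^2
  cv <- tab$rho * tab$se_theta * tab$se_gamma
  det <- s2 * d2 - cv^2
  if (any(det <= 0)) stop("per-study covariance not positive definite")
  r1 <- tab$theta_hat - params$alpha - params$beta * params$gammas
  r2 <- tab$gamma_hat - params$gammas
  quad <- (d2 * r1^2 - 2 * cv * r1 * r2 + s2 * r2^2) / det
  sum(-log(2 * pi) - 0.5 * log(det) - 0.5 * quad)
}

#' Factorized log-likelihood (marginal x conditional form)
#'
#' Evaluates the identical likelihood through the factorization
#' `gamma_hat_i ~ N(gamma_i, delta_i^2)` times
#' `theta_hat_i | gamma_hat_i ~ N(mu_i(gamma_hat_i), v_i^2 + tau2)` with
#' `mu_i(gamma_hat_i) = alpha + beta gamma_i + (rho_i sigma_i / delta_i)
#' (gamma_hat_i - gamma_i)` and `v_i^2 = sigma_i^2 (1 - rho_i^2)`. Agreement
#' with [loglik_marginal()] to machine precision certifies both encodings.
#'
#' @inheritParams loglik_marginal
#' @return scalar log-likelihood.
#' @export
loglik_factorized <- function(tab, params) {
  check_alignment(tab, params)
  dq <- derive_quantities(tab, params)
  s <- dq$v2 + params$tau2
  sum(stats::dnorm(tab$gamma_hat, params$gammas, tab$se_gamma, log = TRUE)) +
    sum(-0.5 * log(2 * pi * s) - 0.5 * dq$residual^2 / s)
}

# Negative log-likelihood and analytic gradient in the unconstrained
# optimization coordinates (alpha, beta, log tau2, gamma_1..gamma_n).
# Used by the fitters; gradient is exact, derived from the factorized form.
nll_unconstrained <- function(par, tab) {
  n <- nrow(tab)
  alpha <- par[1L]; beta <- par[2L]; tau2 <- exp(par[3L])
  gammas <- par[4L:(n + 3L)]
  grad_w <- tab$rho * tab$se_theta / tab$se_gamma
  v2 <- tab$se_theta^2 * (1 - tab$rho^2)
  s <- v2 + tau2
  mu <- alpha + beta * gammas + grad_w * (tab$gamma_hat - gammas)
  r1 <- tab$theta_hat - mu
  r2 <- tab$gamma_hat - gammas
  -sum(-0.5 * log(2 * pi * tab$se_gamma^2) - 0.5 * r2^2 / tab$se_gamma^2 -
         0.5 * log(2 * pi * s) - 0.5 * r1^2 / s)
}

nll_gradient_unconstrained <- function(par, tab) {
  n <- nrow(tab)
  alpha <- par[1L]; beta <- par[2L]; tau2 <- exp(par[3L])
  gammas <- par[4L:(n + 3L)]
  grad_w <- tab$rho * tab$se_theta / tab$se_gamma
  v2 <- tab$se_theta^2 * (1 - tab$rho^2)
  s <- v2 + tau2
  mu <- alpha + beta * gammas + grad_w * (tab$gamma_hat - gammas)
  r <- tab$theta_hat - mu
  dg <- (tab$gamma_hat - gammas) / tab$se_gamma^2 + r * (beta - grad_w) / s
  d_alpha <- sum(r / s)
  d_beta <- sum(r * gammas / s)
  d_ltau2 <- tau2 * sum(-0.5 / s + 0.5 * r^2 / s^2)
  -c(d_alpha, d_beta, d_ltau2, dg)
}

# Same pair with tau2 held fixed; coordinates (alpha, beta, gamma_1..gamma_n).
nll_fixed_tau2 <- function(par, tab, tau2) {
  nll_unconstrained(c(par[1L:2L], log(max(tau2, 1e-300)), par[-(1L:2L)]), tab)
}

nll_gradient_fixed_tau2 <- function(par, tab, tau2) {
  g <- nll_gradient_unconstrained(c(par[1L:2L], log(max(tau2, 1e-300)),
                                    par[-(1L:2L)]), tab)
  g[-3L]
}
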