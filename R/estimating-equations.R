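#' Maximum-likelihood update for the true surrogate effects
#'
#' Single application of the fixed-point estimating equation for each
#' `gamma_i`: the generalized-least-squares projection of
#' `(theta_hat_i - alpha, gamma_hat_i)` onto the design vector `(beta, 1)`
#' under the inverse of the per-study 2x2 marginal covariance. The 2x2
#' adjoint reduces the projection to a scalar closed form; its output zeroes
#' the analytic gamma_i-score of the marginal log-likelihood exactly.
#'
#' @param tab a `study_table` (any number of rows; the update is per-study).
#' @param alpha,beta current regression parameters.
#' @param tau2 current between-study variance, >= 0.
#' @return numeric vector of updated gamma values, one per study.
#' @export
gamma_update <- function(tab, alpha, beta, tau2) {
  stopifnot(tau2 >= 0)
  sigma <- tab$se_theta; delta <- tab$se_gamma; rho <- tab$rho
  s2 <- sigma^2 + tau2
  cv <- rho * sigma * delta
  # adjoint form: determinant cancels between numerator and denominator
  D <- beta^2 * delta^2 - 2 * beta * cv + s2
  num <- (beta * delta^2 - cv) * (tab$theta_hat - alpha) + (s2 - beta * cv) * tab$gamma_hat
  num / D
}

#' Maximum-likelihood update for the between-study regression
#'
#' Joint update of `(alpha, beta)` given current gammas and tau2: the
#' conditional model for `theta_hat_i | gamma_hat_i` is a weighted linear
#' regression with offset `(rho_i sigma_i / delta_i)(gamma_hat_i - gamma_i)`,
#' covariate `gamma_i` and weights `1 / (v_i^2 + tau2)`, so the score
#' equations for alpha and beta are solved by closed-form weighted least
#' squares.
#'
#' @param tab a `study_table` with at least two studies.
#' @param gammas current true surrogate effects (length = number of studies).
#' @param tau2 current between-study variance, >= 0.
#' @return named numeric vector `c(alpha = ..., beta = ...)`.
#' @export
alpha_beta_update <- function(tab, gammas, tau2) {
  stopifnot(tau2 >= 0, length(gammas) == nrow(tab))
  grad_w <- tab$rho * tab$se_theta / tab$se_gamma
  v2 <- tab$se_theta^2 * (1 - tab$rho^2)
  w <- 1 / (v2 + tau2)
  y <- tab$theta_hat - grad_w * (tab$gamma_hat - gammas)
  sw <- sum(w); swx <- sum(w * gammas); swx2 <- sum(w * gammas^2)
  det <- sw * swx2 - swx^2
  if (det <= 1e-12 * sw * max(swx2, 1)) {
    stop("singular design: gammas are (numerically) all identical")
  }
  swy <- sum(w * y); swxy <- sum(w * gammas * y)
  alpha <- (swx2 * swy - swx * swxy) / det
  beta <- (sw * swxy - swx * swy) / det
  c(alpha = alpha, beta = beta)
}

#' Fixed-point update for the between-study variance
#'
#' Single application of the tau2 estimating equation: a weighted average of
#' `(theta_hat_i - mu_i)^2 - v_i^2` with weights `1 / (v_i^2 + tau2)^2`,
#' where `mu_i` uses the gammas stored in `params` and the weights use
#' `params$tau2`. A negative solution is truncated to zero.
#'
#' @param tab a `study_table`.
#' @param params a `param_state` supplying alpha, beta, gammas and the tau2
#'   appearing on the right-hand side.
#' @return list with `raw` (untruncated value) and `tau2 = max(raw, 0)`.
#' @export
tau2_update <- function(tab, params) {
  check_alignment(tab, params)
  grad_w <- tab$rho * tab$se_theta / tab$se_gamma
  v2 <- tab$se_theta^2 * (1 - tab$rho^2)
  mu <- params$alpha + params$beta * params$gammas +
    grad_w * (tab$gamma_hat - params$gammas)
  w <- 1 / (v2 + params$tau2)^2
  raw <- sum(w * ((tab$theta_hat - mu)^2 - v2)) / sum(w)
  list(raw = raw, tau2 = max(raw, 0))
}

#' Estimating-equation residuals at a parameter state
#'
#' Evaluates every maximum-likelihood estimating equation at `params` and
#' returns signed discrepancies (current value minus single-equation
#' update). A certified solution has `max_abs` below the fit tolerance; this
#' is the convergence check that removes doubt that a numerical optimizer
#' has found the correct solution in the (n + 3)-dimensional problem.
#'
#' When `tau2` sits at the truncation boundary (<= `boundary_tol`), the
#' variance equation is satisfied in the Karush-Kuhn-Tucker sense: the
#' residual is the positive part of the untruncated update at tau2 = 0 (a
#' genuine root at zero has a non-positive raw update).
#'
#' @param tab a `study_table`.
#' @param params a `param_state`.
#' @param tau2_equation which variance equation to check: `"mle"` (the
#'   unadjusted fixed point), `"adjusted"` (the bias-adjusted fixed point) or
#'   `"none"` (tau2 treated as externally fixed, e.g. inside a constrained
#'   fit step).
#' @param boundary_tol tau2 values at or below this are treated as truncated
#'   to zero.
#' @return list of class `"ee_residuals"` with `gamma_residuals`,
#'   `alpha_residual`, `beta_residual`, `tau2_residual` and `max_abs`.
#' @export
ee_residuals <- function(tab, params, tau2_equation = c("mle", "adjusted", "none"),
                         boundary_tol = 1e-8) {
  tau2_equation <- match.arg(tau2_equation)
  check_alignment(tab, params)
  g_res <- params$gammas - gamma_update(tab, params$alpha, params$beta, params$tau2)
  ab <- alpha_beta_update(tab, params$gammas, params$tau2)
  a_res <- params$alpha - ab[["alpha"]]
  b_res <- params$beta - ab[["beta"]]
  t_res <- 0
  if (tau2_equation != "none") {
    upd <- if (tau2_equation == "mle") tau2_update else tau2_adjusted_update
    if (params$tau2 > boundary_tol) {
      t_res <- params$tau2 - upd(tab, params)$raw
    } else {
      at_zero <- param_state(params$alpha, params$beta, 0, params$gammas)
      t_res <- max(0, upd(tab, at_zero)$raw)
    }
  }
  out <- list(gamma_residuals = g_res, alpha_residual = a_res,
              beta_residual = b_res, tau2_residual = t_res,
              max_abs = max(abs(c(g_res, a_res, b_res, t_res))))
  class(out) <- "ee_residuals"
  out
}

#' @export
print.ee_residuals <- function(x, ...) {
  cat(sprintf("estimating-equation residuals: max |.| = %.3e\n", x$max_abs))
  cat(sprintf("  alpha %.3e  beta %.3e  tau2 %.3e  max|gamma| %.3e\n",
              x$alpha_residual, x$beta_residual, x$tau2_residual,
              max(abs(x$gamma_residuals))))
  invisible(x)
}
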