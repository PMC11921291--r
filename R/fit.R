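#' Fitting options
#'
#' @param method `"mle"` for conventional maximum likelihood or `"adjusted"`
#'   for the bias-adjusted analysis.
#' @param max_iterations optimizer / fixed-point iteration cap.
#' @param tolerance convergence threshold applied both to parameter changes
#'   and to the estimating-equation certification residuals.
#' @param ci_level confidence level for Wald intervals.
#' @param tau2_zero_threshold tau2 estimates below this are declared 0
#'   (the operational meaning of "very large negative log(tau2)").
#' @param seed optional integer used only for jittered multi-start restarts.
#' @return list of class `"fit_options"`.
#' @export
fit_options <- function(method = c("mle", "adjusted"), max_iterations = 500L,
                        tolerance = 1e-6, ci_level = 0.95,
                        tau2_zero_threshold = 1e-8, seed = NULL) {
  method <- match.arg(method)
  stopifnot(tolerance > 0, ci_level > 0, ci_level < 1, max_iterations >= 1)
  structure(list(method = method, max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, ci_level = ci_level,
                 tau2_zero_threshold = tau2_zero_threshold, seed = seed),
            class = "fit_options")
}

#' Bias-adjustment terms
#'
#' Per-study term `b_i = (beta delta_i - rho_i sigma_i)^2 /
#' ((beta delta_i - rho_i sigma_i)^2 + tau2 + v_i^2)`, always in `[0, 1)`.
#' `b_i = 0` exactly when the between-study gradient `beta` equals the
#' within-study gradient `rho_i sigma_i / delta_i`; the adjustment grows
#' with the squared gap between the two gradients.
#'
#' @param tab a `study_table`.
#' @param beta between-study slope estimate.
#' @param tau2 between-study variance estimate, >= 0.
#' @return numeric vector of length `nrow(tab)`.
#' @export
bias_terms <- function(tab, beta, tau2) {
  stopifnot(tau2 >= 0)
  gap2 <- (beta * tab$se_gamma - tab$rho * tab$se_theta)^2
  v2 <- tab$se_theta^2 * (1 - tab$rho^2)
  gap2 / (gap2 + tau2 + v2)
}

#' Bias-adjusted fixed-point update for the between-study variance
#'
#' As [tau2_update()], but each squared residual is inflated by
#' `(1 - b_i)^-2` with `b_i` from [bias_terms()] evaluated at the current
#' beta and tau2. Since `(1 - b_i)^-2 >= 1` the untruncated value is never
#' below the unadjusted one at the same parameter values. A negative
#' solution is truncated to zero.
#'
#' @inheritParams tau2_update
#' @return list with `raw` and `tau2 = max(raw, 0)`.
#' @export
tau2_adjusted_update <- function(tab, params) {
  check_alignment(tab, params)
  b <- bias_terms(tab, params$beta, params$tau2)
  grad_w <- tab$rho * tab$se_theta / tab$se_gamma
  v2 <- tab$se_theta^2 * (1 - tab$rho^2)
  mu <- params$alpha + params$beta * params$gammas +
    grad_w * (tab$gamma_hat - params$gammas)
  w <- 1 / (v2 + params$tau2)^2
  raw <- sum(w * ((1 - b)^-2 * (tab$theta_hat - mu)^2 - v2)) / sum(w)
  list(raw = raw, tau2 = max(raw, 0))
}

# Starting values: gammas at their direct estimates, (alpha, beta) from WLS
# of theta_hat on gamma_hat with weights 1/sigma^2, tau2 from one
# fixed-point step floored at 1e-4.
starting_values <- function(tab) {
  w <- 1 / tab$se_theta^2
  x <- tab$gamma_hat; y <- tab$theta_hat
  sw <- sum(w); swx <- sum(w * x); swx2 <- sum(w * x^2)
  det <- sw * swx2 - swx^2
  if (abs(det) > 1e-12 * sw * max(swx2, 1)) {
    alpha <- (swx2 * sum(w * y) - swx * sum(w * x * y)) / det
    beta <- (sw * sum(w * x * y) - swx * sum(w * y)) / det
  } else {
    alpha <- sum(w * y) / sw; beta <- 0
  }
  p0 <- param_state(alpha, beta, 0, tab$gamma_hat)
  tau2 <- max(tau2_update(tab, p0)$tau2, 1e-4)
  param_state(alpha, beta, tau2, tab$gamma_hat)
}

# A few sweeps of the fixed-point estimating equations, used to polish an
# optimizer solution so that the certification residuals reach machine-level
# roots. tau2_equation = "none" keeps tau2 fixed (constrained fits).
fixed_point_polish <- function(tab, params, tau2_equation = "mle",
                               max_iter = 200L, tol = 1e-10) {
  upd <- switch(tau2_equation, mle = tau2_update,
                adjusted = tau2_adjusted_update, none = NULL)
  for (it in seq_len(max_iter)) {
    old <- c(params$alpha, params$beta, params$tau2, params$gammas)
    params$gammas <- gamma_update(tab, params$alpha, params$beta, params$tau2)
    ab <- alpha_beta_update(tab, params$gammas, params$tau2)
    params$alpha <- ab[["alpha"]]; params$beta <- ab[["beta"]]
    if (!is.null(upd)) params$tau2 <- upd(tab, params)$tau2
    if (max(abs(old - c(params$alpha, params$beta, params$tau2,
                        params$gammas))) < tol) break
  }
  params
}

run_nlminb <- function(start_par, tab, options) {
  stats::nlminb(start_par, nll_unconstrained,
                gradient = nll_gradient_unconstrained, tab = tab,
                control = list(iter.max = options$max_iterations,
                               eval.max = 4L * options$max_iterations))
}

#' Fit the model by conventional maximum likelihood
#'
#' Maximizes the marginal log-likelihood numerically over
#' `(alpha, beta, log tau2, gamma_1..gamma_n)` (dimension n + 3, all
#' coordinates unconstrained) by quasi-Newton iteration with analytic
#' gradients, then certifies the solution by substituting it into every
#' estimating equation ([ee_residuals()]). If certification fails, the
#' solution is polished by fixed-point sweeps and up to three jittered
#' restarts are attempted; persistent failure is reported in the
#' `converged` flag, never silently accepted. tau2 estimates below
#' `tau2_zero_threshold` are truncated to zero, in which case standard
#' errors come from the generalized-inverse (constrained) Hessian.
#'
#' @param tab a `study_table` with at least 3 studies.
#' @param options a [fit_options()] list.
#' @return object of class `"dh_fit"`; see [print.dh_fit()].
#' @export
fit_mle <- function(tab, options = fit_options("mle")) {
  tab <- validate_study_table(tab)
  n <- nrow(tab)
  if (n < 3L) {
    stop("under-identified: need at least 3 studies (n + 3 parameters vs 2n observations)")
  }
  start <- starting_values(tab)
  par0 <- c(start$alpha, start$beta, log(start$tau2), start$gammas)
  best <- NULL
  tries <- list(par0)
  if (!is.null(options$seed)) set.seed(options$seed)
  for (k in seq_len(4L)) {
    if (k > length(tries)) break
    opt <- run_nlminb(tries[[k]], tab, options)
    tau2_hat <- exp(opt$par[3L])
    truncated <- tau2_hat < options$tau2_zero_threshold
    params <- param_state(opt$par[1L], opt$par[2L],
                          if (truncated) 0 else tau2_hat,
                          opt$par[4L:(n + 3L)])
    params <- fixed_point_polish(tab, params, "mle",
                                 max_iter = options$max_iterations)
    truncated <- params$tau2 < options$tau2_zero_threshold
    if (truncated) params$tau2 <- 0
    res <- ee_residuals(tab, params, "mle",
                        boundary_tol = options$tau2_zero_threshold)
    ll <- loglik_marginal(tab, params)
    cand <- list(params = params, res = res, loglik = ll, truncated = truncated)
    if (is.null(best) || (res$max_abs < best$res$max_abs) ||
        (res$max_abs <= options$tolerance && ll > best$loglik)) {
      best <- cand
    }
    if (best$res$max_abs <= options$tolerance) break
    # jittered restart around the starting values
    tries[[k + 1L]] <- par0 + c(stats::rnorm(2L, 0, 0.25), stats::rnorm(1L, 0, 0.5),
                                stats::rnorm(n, 0, 0.25))
  }
  finish_fit(tab, best, options, method = "mle",
             bias = rep(0, n), tau2_known = FALSE)
}

# Constrained maximization over (alpha, beta, gammas) with tau2 fixed.
fit_constrained <- function(tab, tau2, start_params, options) {
  n <- nrow(tab)
  par0 <- c(start_params$alpha, start_params$beta, start_params$gammas)
  opt <- stats::nlminb(par0, nll_fixed_tau2, gradient = nll_gradient_fixed_tau2,
                       tab = tab, tau2 = tau2,
                       control = list(iter.max = options$max_iterations,
                                      eval.max = 4L * options$max_iterations))
  params <- param_state(opt$par[1L], opt$par[2L], tau2, opt$par[3L:(n + 2L)])
  fixed_point_polish(tab, params, "none", max_iter = options$max_iterations)
}

#' Fit the model with the bias-adjusted between-study variance
#'
#' Alternates to a joint fixed point: (a) given the current tau2, maximize
#' the likelihood over `(alpha, beta, gamma_1..gamma_n)` under that
#' constraint; (b) update tau2 by the bias-adjusted estimating equation
#' ([tau2_adjusted_update()]) at the refitted parameters. Iteration starts
#' from the conventional maximum likelihood fit and stops when the tau2
#' change falls below `tol` (1e-8) or after `max_iterations`; a solution
#' truncated at zero is terminal once the update returns zero twice in a
#' row. With `mode = "single_pass"` the adjusted equation is instead
#' evaluated once at the MLE quantities followed by a single constrained
#' refit. Standard errors for `(alpha, beta)` come from the constrained fit,
#' treating the adjusted tau2 as known.
#'
#' @inheritParams fit_mle
#' @param mode `"iterate"` (default, joint fixed point) or `"single_pass"`.
#' @return object of class `"dh_fit"` with `method = "adjusted"`.
#' @export
fit_adjusted <- function(tab, options = fit_options("adjusted"),
                         mode = c("iterate", "single_pass")) {
  mode <- match.arg(mode)
  options$method <- "adjusted"
  mle <- fit_mle(tab, options)
  params <- mle$estimates
  tau2_tol <- 1e-8
  zeros_in_a_row <- 0L
  converged_fp <- FALSE
  max_outer <- if (mode == "single_pass") 1L else 200L
  for (it in seq_len(max_outer)) {
    upd <- tau2_adjusted_update(tab, params)
    tau2_new <- upd$tau2
    if (tau2_new == 0) zeros_in_a_row <- zeros_in_a_row + 1L else zeros_in_a_row <- 0L
    delta <- abs(tau2_new - params$tau2)
    params <- fit_constrained(tab, tau2_new, params, options)
    if (mode == "single_pass") { converged_fp <- TRUE; break }
    if (delta < tau2_tol || zeros_in_a_row >= 2L) { converged_fp <- TRUE; break }
  }
  truncated <- params$tau2 < options$tau2_zero_threshold
  if (truncated) params$tau2 <- 0
  res <- ee_residuals(tab, params, if (mode == "iterate") "adjusted" else "none",
                      boundary_tol = options$tau2_zero_threshold)
  best <- list(params = params, res = res,
               loglik = loglik_marginal(tab, params),
               truncated = truncated, fp_converged = converged_fp)
  finish_fit(tab, best, options, method = "adjusted",
             bias = bias_terms(tab, params$beta, params$tau2), tau2_known = TRUE)
}

# Assemble a dh_fit object: SEs, Wald intervals, flags.
finish_fit <- function(tab, best, options, method, bias, tau2_known) {
  params <- best$params
  se <- tryCatch(standard_errors(tab, params, tau2_known = tau2_known),
                 error = function(e) {
                   warning(conditionMessage(e))
                   list(alpha = NA_real_, beta = NA_real_, log_tau2 = NA_real_)
                 })
  ci <- list(alpha = wald_interval(params$alpha, se$alpha, options$ci_level),
             beta = wald_interval(params$beta, se$beta, options$ci_level))
  converged <- best$res$max_abs <= options$tolerance &&
    is.finite(se$alpha) && is.finite(se$beta) &&
    !isFALSE(best$fp_converged)
  structure(list(method = method, estimates = params,
                 alpha = params$alpha, beta = params$beta, tau2 = params$tau2,
                 se = se, ci = ci, ci_level = options$ci_level,
                 bias_terms = bias, tau2_truncated = best$truncated,
                 ee_max_abs = best$res$max_abs, ee_residuals = best$res,
                 converged = converged, loglik = best$loglik,
                 n = nrow(tab)),
            class = "dh_fit")
}

#' Fit the model by a named method
#'
#' Thin dispatcher over [fit_mle()], [fit_adjusted()] and [fit_bayes()].
#'
#' @param tab a `study_table`.
#' @param method one of `"mle"`, `"adjusted"`, `"bayes"`.
#' @param options a [fit_options()] (frequentist) or [mcmc_options()]
#'   (Bayesian) list; defaults chosen per method.
#' @param ... passed on to the method-specific fitter.
#' @return a `"dh_fit"` (frequentist) or `"dh_bayes_fit"` (Bayesian) object.
#' @export
fit_model <- function(tab, method = c("mle", "adjusted", "bayes"),
                      options = NULL, ...) {
  method <- match.arg(method)
  switch(method,
         mle = fit_mle(tab, options %||% fit_options("mle"), ...),
         adjusted = fit_adjusted(tab, options %||% fit_options("adjusted"), ...),
         bayes = fit_bayes(tab, options %||% mcmc_options(), ...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standard errors from the numerically differentiated Hessian
#'
#' Central-difference Hessian of the negative log-likelihood in the
#' `(alpha, beta, log tau2, gamma_1..gamma_n)` parameterization (relative
#' step 1e-5 per coordinate, differencing the analytic gradient), inverted
#' by a symmetric generalized inverse with eigenvalue truncation at relative
#' tolerance 1e-10. When the tau2 estimate is zero, or tau2 is treated as
#' known (`tau2_known = TRUE`, the adjusted analysis), the log tau2
#' coordinate is dropped, which is numerically equivalent to constraining
#' tau2 at its value.
#'
#' @param tab a `study_table`.
#' @param params a `param_state` at a (possibly constrained) optimum.
#' @param tau2_known logical; treat tau2 as fixed when differentiating.
#' @return list with elements `alpha`, `beta`, `log_tau2` (NA when the
#'   coordinate is dropped), `gammas`, and the full `vcov` matrix.
#' @export
standard_errors <- function(tab, params, tau2_known = FALSE) {
  check_alignment(tab, params)
  n <- nrow(tab)
  drop_tau2 <- tau2_known || params$tau2 <= 0
  if (drop_tau2) {
    par <- c(params$alpha, params$beta, params$gammas)
    gr <- function(p) nll_gradient_fixed_tau2(p, tab, params$tau2)
  } else {
    par <- c(params$alpha, params$beta, log(params$tau2), params$gammas)
    gr <- function(p) nll_gradient_unconstrained(p, tab)
  }
  H <- central_diff_hessian(gr, par)
  V <- sym_ginv(H, rel_tol = 1e-10)
  d <- diag(V)
  if (any(d[1:2] < 0, na.rm = TRUE)) {
    stop("Hessian not positive semi-definite at the claimed optimum")
  }
  se <- sqrt(pmax(d, 0))
  if (drop_tau2) {
    list(alpha = se[1L], beta = se[2L], log_tau2 = NA_real_,
         gammas = se[3L:(n + 2L)], vcov = V)
  } else {
    list(alpha = se[1L], beta = se[2L], log_tau2 = se[3L],
         gammas = se[4L:(n + 3L)], vcov = V)
  }
}

central_diff_hessian <- function(gr, par, rel_step = 1e-5) {
  k <- length(par)
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    h <- rel_step * max(1, abs(par[j]))
    up <- par; up[j] <- up[j] + h
    dn <- par; dn[j] <- dn[j] - h
    H[, j] <- (gr(up) - gr(dn)) / (2 * h)
  }
  (H + t(H)) / 2
}

sym_ginv <- function(H, rel_tol = 1e-10) {
  # Jacobi scaling first so the eigenvalue truncation is invariant to the
  # (often extreme) spread of per-coordinate curvatures
  d <- diag(H)
  s <- ifelse(d > 0, 1 / sqrt(d), 1)
  Hs <- H * tcrossprod(s)
  e <- eigen(Hs, symmetric = TRUE)
  keep <- abs(e$values) > rel_tol * max(abs(e$values), .Machine$double.eps)
  vals_inv <- ifelse(keep, 1 / e$values, 0)
  Vs <- e$vectors %*% (vals_inv * t(e$vectors))
  Vs * tcrossprod(s)
}

#' Wald confidence interval
#'
#' `estimate +/- z_{(1 + level)/2} * se` with the exact normal quantile.
#'
#' @param estimate point estimate.
#' @param se standard error, >= 0 (NA propagates).
#' @param level confidence level in (0, 1).
#' @return numeric vector `c(lower, upper)`.
#' @export
wald_interval <- function(estimate, se, level = 0.95) {
  stopifnot(level > 0, level < 1)
  z <- stats::qnorm((1 + level) / 2)
  c(lower = estimate - z * se, upper = estimate + z * se)
}

#' @export
print.dh_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Daniels-Hughes model fit (%s), %d studies\n",
              ifelse(x$method == "mle", "maximum likelihood", "bias-adjusted"),
              x$n))
  fmt <- function(est, ci) sprintf(paste0("%.", digits, "f (%.", digits,
                                          "f, %.", digits, "f)"),
                                   est, ci[1L], ci[2L])
  cat(sprintf("  alpha: %s\n", fmt(x$alpha, x$ci$alpha)))
  cat(sprintf("  beta : %s\n", fmt(x$beta, x$ci$beta)))
  cat(sprintf("  tau2 : %.*f%s\n", digits, x$tau2,
              if (x$tau2_truncated) " (truncated at 0)" else ""))
  cat(sprintf("  log-likelihood %.4f; estimating-equation max residual %.2e; %s\n",
              x$loglik, x$ee_max_abs,
              if (x$converged) "converged" else "NOT certified"))
  invisible(x)
}
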