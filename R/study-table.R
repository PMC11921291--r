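#' Construct a study table of paired treatment-effect estimates
#'
#' A study table holds the aggregate data consumed by the Daniels-Hughes
#' bivariate meta-analysis model: for each study, the estimated treatment
#' effect on the clinical outcome (`theta_hat`, e.g. a log hazard ratio for
#' overall survival), the estimated effect on the candidate surrogate
#' (`gamma_hat`, e.g. a log hazard ratio for progression-free survival),
#' their within-study standard errors, and the within-study correlation
#' between the two estimates. All effects are on the log (linear-predictor)
#' scale; the package never exponentiates.
#'
#' @param theta_hat numeric, estimated effect on the clinical outcome.
#' @param se_theta numeric, within-study standard error of `theta_hat` (> 0).
#' @param gamma_hat numeric, estimated effect on the surrogate.
#' @param se_gamma numeric, within-study standard error of `gamma_hat` (> 0).
#' @param rho within-study correlation(s) in (-1, 1); a single value is
#'   recycled to all studies.
#' @param label study identifiers; must be unique.
#'
#' @return A `data.frame` of class `"study_table"` with columns `label`,
#'   `theta_hat`, `se_theta`, `gamma_hat`, `se_gamma`, `rho`.
#' @examples
#' study_table(theta_hat = c(-0.2, -0.1, -0.4), se_theta = c(0.1, 0.2, 0.15),
#'             gamma_hat = c(-0.3, -0.2, -0.5), se_gamma = c(0.1, 0.2, 0.15),
#'             rho = 0.5)
#' @export
study_table <- function(theta_hat, se_theta, gamma_hat, se_gamma, rho,
                        label = NULL) {
  n <- length(theta_hat)
  if (length(rho) == 1L) rho <- rep(rho, n)
  if (is.null(label)) label <- paste0("study_", seq_len(n))
  lens <- c(length(se_theta), length(gamma_hat), length(se_gamma),
            length(rho), length(label))
  if (any(lens != n)) {
    stop("all columns must have the same length (n = ", n, ")")
  }
  tab <- data.frame(label = as.character(label),
                    theta_hat = as.numeric(theta_hat),
                    se_theta = as.numeric(se_theta),
                    gamma_hat = as.numeric(gamma_hat),
                    se_gamma = as.numeric(se_gamma),
                    rho = as.numeric(rho),
                    stringsAsFactors = FALSE)
  class(tab) <- c("study_table", "data.frame")
  validate_study_table(tab)
}

#' Validate a study table
#'
#' Checks the invariants required by the within-study model: positive
#' standard errors, correlations bounded away from +/-1 (so the conditional
#' within-study variance sigma^2 (1 - rho^2) stays positive), unique study
#' labels and finite numeric values.
#'
#' @param tab an object coercible to `study_table`.
#' @return `tab`, invisibly classed as `study_table`, or an error.
#' @export
validate_study_table <- function(tab) {
  required <- c("label", "theta_hat", "se_theta", "gamma_hat", "se_gamma", "rho")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  num_cols <- setdiff(required, "label")
  for (col in num_cols) {
    bad <- which(!is.finite(tab[[col]]))
    if (length(bad)) {
      stop("non-finite value in column '", col, "', row ", bad[1L])
    }
  }
  bad <- which(tab$se_theta <= 0)
  if (length(bad)) stop("se_theta must be > 0; offending row ", bad[1L])
  bad <- which(tab$se_gamma <= 0)
  if (length(bad)) stop("se_gamma must be > 0; offending row ", bad[1L])
  bad <- which(abs(tab$rho) >= 1 - 1e-6)
  if (length(bad)) {
    stop("rho must lie strictly inside (-1, 1); offending row ", bad[1L])
  }
  if (anyDuplicated(tab$label)) stop("study labels must be unique")
  if (!inherits(tab, "study_table")) class(tab) <- c("study_table", class(tab))
  tab
}

#' Number of studies in a study table
#' @param tab a `study_table`.
#' @return integer count of studies.
#' @export
n_studies <- function(tab) nrow(tab)

#' Construct the full parameter state of the marginal model
#'
#' The marginal model carries an intercept `alpha` and slope `beta` for the
#' between-study regression of the true clinical effect on the true
#' surrogate effect, the conditional between-study variance `tau2`, and one
#' true surrogate effect `gamma_i` per study (the incidental parameters).
#'
#' @param alpha intercept of the between-study regression.
#' @param beta slope (the "between-study gradient").
#' @param tau2 conditional between-study variance, >= 0.
#' @param gammas numeric vector of true surrogate effects, one per study.
#' @return list of class `"param_state"`.
#' @export
param_state <- function(alpha, beta, tau2, gammas) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L,
            is.numeric(beta), length(beta) == 1L,
            is.numeric(tau2), length(tau2) == 1L,
            is.numeric(gammas), length(gammas) >= 1L)
  if (tau2 < 0) stop("tau2 must be >= 0")
  structure(list(alpha = alpha, beta = beta, tau2 = tau2,
                 gammas = as.numeric(gammas)),
            class = "param_state")
}

check_alignment <- function(tab, params) {
  if (length(params$gammas) != nrow(tab)) {
    stop("length(gammas) = ", length(params$gammas),
         " does not match the number of studies (", nrow(tab), ")")
  }
  invisible(TRUE)
}

#' Per-study derived quantities of the model
#'
#' Computes, for each study, the terms that recur throughout estimation:
#' the conditional within-study variance `v2 = sigma^2 (1 - rho^2)`, the
#' within-study gradient `rho * sigma / delta` (the slope of
#' E(theta_hat | gamma_hat) inside a study), the conditional mean
#' `mu = alpha + beta * gamma + (rho sigma / delta) (gamma_hat - gamma)`,
#' the residual `theta_hat - mu`, the first weight-vector entry `w1` of the
#' generalized-least-squares projection onto the design vector `(beta, 1)`,
#' and the bias-adjustment term `b = (beta - rho sigma / delta) * w1`, which
#' always lies in `[0, 1)`.
#'
#' @param tab a `study_table`.
#' @param params a `param_state` aligned with `tab`.
#' @return data.frame with one row per study and columns `v2`,
#'   `within_gradient`, `mu`, `residual`, `w1`, `b`.
#' @export
derive_quantities <- function(tab, params) {
  check_alignment(tab, params)
  sigma <- tab$se_theta
  delta <- tab$se_gamma
  rho <- tab$rho
  beta <- params$beta
  tau2 <- params$tau2
  v2 <- sigma^2 * (1 - rho^2)
  grad <- rho * sigma / delta
  mu <- params$alpha + beta * params$gammas + grad * (tab$gamma_hat - params$gammas)
  # denominator of the 2x2 adjoint projection; equals (beta*delta - rho*sigma)^2
  # + tau2 + v2, hence always > 0
  D <- sigma^2 + tau2 + beta^2 * delta^2 - 2 * beta * rho * sigma * delta
  w1 <- (beta * delta^2 - rho * sigma * delta) / D
  b <- (beta - grad) * w1
  data.frame(v2 = v2, within_gradient = grad, mu = mu,
             residual = tab$theta_hat - mu, w1 = w1, b = b)
}

#' Per-study weight matrix of the reparameterized model
#'
#' The inverse of the 2x2 marginal covariance of `(theta_hat - alpha,
#' gamma_hat)`, computed by the closed-form adjoint.
#'
#' @param study one row of a `study_table`.
#' @param tau2 between-study variance.
#' @return a symmetric positive-definite 2x2 matrix.
#' @export
study_weight_matrix <- function(study, tau2) {
  s2 <- study$se_theta^2 + tau2
  d2 <- study$se_gamma^2
  cv <- study$rho * study$se_theta * study$se_gamma
  det <- s2 * d2 - cv^2
  matrix(c(d2, -cv, -cv, s2), 2L, 2L) / det
}

#' @export
print.study_table <- function(x, ...) {
  cat("Study table:", nrow(x), "studies\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
print.param_state <- function(x, ...) {
  cat(sprintf("alpha = %.4f, beta = %.4f, tau2 = %.4f, n gammas = %d\n",
              x$alpha, x$beta, x$tau2, length(x$gammas)))
  invisible(x)
}
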