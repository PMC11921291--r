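#' MCMC options for the reference Bayesian analysis
#'
#' Defaults mirror a conventional vague-prior analysis of this model:
#' independent N(0, 1000) priors for alpha, beta and every gamma_i, a
#' uniform prior on the between-study standard deviation tau over
#' (0, `tau_upper`), a burn-in of 1000 iterations and 10,000 further
#' iterations thinned by two.
#'
#' @param burn_in discarded initial iterations.
#' @param kept_iterations post-burn-in iterations (before thinning).
#' @param thinning keep every `thinning`-th draw.
#' @param seed integer seed; draws are bit-reproducible given it.
#' @param prior_sd_regression prior SD for alpha, beta, gamma_i
#'   (default sqrt(1000)).
#' @param tau_upper upper bound of the uniform prior on tau.
#' @return list of class `"mcmc_options"`.
#' @export
mcmc_options <- function(burn_in = 1000L, kept_iterations = 10000L,
                         thinning = 2L, seed = NULL,
                         prior_sd_regression = sqrt(1000), tau_upper = 2) {
  stopifnot(burn_in >= 0, kept_iterations > 0, thinning >= 1, tau_upper > 0,
            prior_sd_regression > 0)
  structure(list(burn_in = as.integer(burn_in),
                 kept_iterations = as.integer(kept_iterations),
                 thinning = as.integer(thinning), seed = seed,
                 prior_sd_regression = prior_sd_regression,
                 tau_upper = tau_upper),
            class = "mcmc_options")
}

#' Draw from the posterior by Metropolis-within-Gibbs
#'
#' Component-wise sampler for the model under the vague priors of
#' [mcmc_options()]: alpha, beta and each gamma_i have conjugate normal
#' full conditionals under the factorized likelihood and are drawn exactly;
#' tau is updated on the standard-deviation scale by a random-walk
#' Metropolis step (normal proposal, SD `0.1 * tau_upper`) reflected into
#' `(0, tau_upper)`, matching the uniform prior support.
#'
#' @param tab a `study_table` with fixed within-study correlations.
#' @param options an [mcmc_options()] list.
#' @param use_likelihood set `FALSE` to sample from the prior only
#'   (prior-predictive check); data are then ignored.
#' @return matrix of class `"dh_chains"` with one kept draw per row and
#'   columns `alpha`, `beta`, `tau2`, `gamma_1..gamma_n`. A `warnings`
#'   attribute carries chain diagnostics (e.g. tau stuck at the boundary).
#' @export
sample_posterior <- function(tab, options = mcmc_options(),
                             use_likelihood = TRUE) {
  tab <- validate_study_table(tab)
  n <- nrow(tab)
  if (!is.null(options$seed)) set.seed(options$seed)
  c2 <- options$prior_sd_regression^2
  U <- options$tau_upper
  g_w <- tab$rho * tab$se_theta / tab$se_gamma
  v2 <- tab$se_theta^2 * (1 - tab$rho^2)
  d2 <- tab$se_gamma^2
  # initial state: moment starts (prior draws when likelihood is off)
  if (use_likelihood) {
    st <- starting_values(tab)
    alpha <- st$alpha; beta <- st$beta
    gammas <- tab$gamma_hat
    tau <- sqrt(min(max(st$tau2, 0.01), U^2 * 0.25))
  } else {
    alpha <- 0; beta <- 0; gammas <- rep(0, n); tau <- U / 2
  }
  total <- options$burn_in + options$kept_iterations
  keep_idx <- options$burn_in +
    seq(options$thinning, options$kept_iterations, by = options$thinning)
  out <- matrix(NA_real_, length(keep_idx), n + 3L)
  colnames(out) <- c("alpha", "beta", "tau2", paste0("gamma_", seq_len(n)))
  step <- 0.1 * U
  row <- 0L
  tau_at_boundary <- 0L
  cond_loglik <- function(tau2, mu) {
    s <- v2 + tau2
    sum(-0.5 * log(s) - 0.5 * (tab$theta_hat - mu)^2 / s)
  }
  for (it in seq_len(total)) {
    s <- v2 + tau^2
    if (use_likelihood) {
      # gammas: conjugate normal full conditionals
      prec <- 1 / d2 + (beta - g_w)^2 / s + 1 / c2
      m <- (tab$gamma_hat / d2 +
              (beta - g_w) * (tab$theta_hat - alpha - g_w * tab$gamma_hat) / s) / prec
      gammas <- stats::rnorm(n, m, sqrt(1 / prec))
      # (alpha, beta): bivariate normal full conditional from the weighted
      # regression with offset
      y <- tab$theta_hat - g_w * (tab$gamma_hat - gammas)
      w <- 1 / s
      A11 <- sum(w) + 1 / c2
      A12 <- sum(w * gammas)
      A22 <- sum(w * gammas^2) + 1 / c2
      b1 <- sum(w * y); b2 <- sum(w * gammas * y)
      det <- A11 * A22 - A12^2
      m_a <- (A22 * b1 - A12 * b2) / det
      m_b <- (A11 * b2 - A12 * b1) / det
      # sample via 2x2 Cholesky of the covariance (inverse precision)
      V11 <- A22 / det; V12 <- -A12 / det; V22 <- A11 / det
      L11 <- sqrt(V11); L21 <- V12 / L11; L22 <- sqrt(V22 - L21^2)
      z <- stats::rnorm(2L)
      alpha <- m_a + L11 * z[1L]
      beta <- m_b + L21 * z[1L] + L22 * z[2L]
      # tau: reflecting random-walk Metropolis on the SD scale
      mu <- alpha + beta * gammas + g_w * (tab$gamma_hat - gammas)
      prop <- tau + stats::rnorm(1L, 0, step)
      prop <- reflect_into(prop, 0, U)
      log_acc <- cond_loglik(prop^2, mu) - cond_loglik(tau^2, mu)
      if (log(stats::runif(1L)) < log_acc) tau <- prop
    } else {
      gammas <- stats::rnorm(n, 0, sqrt(c2))
      alpha <- stats::rnorm(1L, 0, sqrt(c2))
      beta <- stats::rnorm(1L, 0, sqrt(c2))
      tau <- stats::runif(1L, 0, U)
    }
    if (tau < 1e-3 * U || tau > U * (1 - 1e-3)) {
      tau_at_boundary <- tau_at_boundary + 1L
    }
    if (it > options$burn_in &&
        (it - options$burn_in) %% options$thinning == 0L) {
      row <- row + 1L
      out[row, ] <- c(alpha, beta, tau^2, gammas)
    }
  }
  warnings <- character()
  if (use_likelihood && tau_at_boundary > 0.5 * total) {
    warnings <- c(warnings,
                  "tau spent more than half the chain at the prior boundary")
  }
  structure(out, class = c("dh_chains", "matrix"),
            seed = options$seed, warnings = warnings)
}

reflect_into <- function(x, lo, hi) {
  width <- hi - lo
  y <- (x - lo) %% (2 * width)
  lo + ifelse(y > width, 2 * width - y, y)
}

#' Summarize posterior chains
#'
#' Posterior mean, median, central 95% percentile interval and 95% highest
#' posterior density interval (shortest sorted window) per parameter.
#'
#' @param chains a `"dh_chains"` matrix from [sample_posterior()].
#' @param level interval probability (default 0.95).
#' @return data.frame of class `"posterior_summary"` with one row per
#'   parameter and columns `mean`, `median`, `pct_lower`, `pct_upper`,
#'   `hpd_lower`, `hpd_upper`, plus an `n_draws` attribute.
#' @export
posterior_summary <- function(chains, level = 0.95) {
  stopifnot(nrow(chains) > 0, level > 0, level < 1)
  a <- (1 - level) / 2
  summ <- do.call(rbind, lapply(colnames(chains), function(nm) {
    x <- chains[, nm]
    q <- stats::quantile(x, c(a, 1 - a), names = FALSE, type = 7)
    h <- hpd_interval(x, level)
    data.frame(parameter = nm, mean = mean(x), median = stats::median(x),
               pct_lower = q[1L], pct_upper = q[2L],
               hpd_lower = h[1L], hpd_upper = h[2L])
  }))
  attr(summ, "n_draws") <- nrow(chains)
  class(summ) <- c("posterior_summary", "data.frame")
  summ
}

#' Highest posterior density interval from draws
#'
#' Shortest window containing a fraction `level` of the sorted draws.
#'
#' @param x numeric draws.
#' @param level interval probability.
#' @return numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(x, level = 0.95) {
  xs <- sort(x)
  m <- length(xs)
  k <- max(1L, ceiling(level * m))
  if (k >= m) return(c(xs[1L], xs[m]))
  widths <- xs[(k + 1L):m] - xs[1L:(m - k)]
  i <- which.min(widths)
  c(xs[i], xs[i + k])
}

#' Bayesian model fit: sample, summarize, package
#'
#' Convenience wrapper running [sample_posterior()] and
#' [posterior_summary()].
#'
#' @param tab a `study_table`.
#' @param options an [mcmc_options()] list.
#' @return list of class `"dh_bayes_fit"` with elements `chains`,
#'   `summary`, `n`.
#' @export
fit_bayes <- function(tab, options = mcmc_options()) {
  chains <- sample_posterior(tab, options)
  structure(list(chains = chains, summary = posterior_summary(chains),
                 n = nrow(tab), options = options),
            class = "dh_bayes_fit")
}

#' @export
print.dh_bayes_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Bayesian fit (Metropolis-within-Gibbs), %d studies, %d draws\n",
              x$n, nrow(x$chains)))
  s <- x$summary[x$summary$parameter %in% c("alpha", "beta", "tau2"), ]
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-5s mean %.*f (%.*f, %.*f) | median %.*f HPD (%.*f, %.*f)\n",
                s$parameter[i], digits, s$mean[i], digits, s$pct_lower[i],
                digits, s$pct_upper[i], digits, s$median[i],
                digits, s$hpd_lower[i], digits, s$hpd_upper[i]))
  }
  invisible(x)
}
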