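#' Read a study table from a delimited text file
#'
#' Expects a CSV with header columns `study`, `theta_hat`, `se_theta`,
#' `gamma_hat`, `se_gamma` and optionally `rho`. Effects must be on the log
#' scale; with `hazard_ratio = TRUE` the `theta_hat`/`gamma_hat` columns are
#' taken as hazard (or odds) ratios and log-transformed at read time, with
#' the standard errors taken as already on the log scale.
#'
#' @param path path to the CSV file.
#' @param shared_rho optional single within-study correlation applied to
#'   every study; overrides/fills the `rho` column. A missing `rho` column
#'   with no `shared_rho` is an error, never a silent zero: choosing the
#'   within-study correlations is a substantive modelling decision.
#' @param hazard_ratio logical; log-transform the effect columns.
#' @return a validated `study_table`.
#' @export
read_study_table <- function(path, shared_rho = NULL, hazard_ratio = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("study", "theta_hat", "se_theta", "gamma_hat", "se_gamma")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(names(raw), "study")) {
    if (!is.numeric(raw[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(raw[[col]]))))[1L]
      stop("non-numeric value in column '", col, "', row ",
           if (is.na(bad)) "?" else bad)
    }
  }
  if (is.null(shared_rho)) {
    if (!"rho" %in% names(raw)) {
      stop("no 'rho' column and no shared_rho given; ",
           "within-study correlations must be supplied explicitly")
    }
    rho <- raw$rho
  } else {
    stopifnot(length(shared_rho) == 1L, abs(shared_rho) < 1)
    rho <- rep(shared_rho, nrow(raw))
  }
  th <- raw$theta_hat; gh <- raw$gamma_hat
  if (hazard_ratio) {
    if (any(th <= 0) || any(gh <= 0)) {
      stop("hazard_ratio = TRUE requires strictly positive effect columns")
    }
    th <- log(th); gh <- log(gh)
  }
  study_table(th, raw$se_theta, gh, raw$se_gamma, rho, label = raw$study)
}

#' Write a study table to CSV
#'
#' Full-precision round-trip counterpart of [read_study_table()].
#'
#' @param tab a `study_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(tab, path) {
  out <- data.frame(study = tab$label, theta_hat = tab$theta_hat,
                    se_theta = tab$se_theta, gamma_hat = tab$gamma_hat,
                    se_gamma = tab$se_gamma, rho = tab$rho)
  utils::write.csv(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Within-study correlation sensitivity analysis
#'
#' Refits the model once per candidate shared within-study correlation and
#' tabulates the estimates, Wald intervals and the range of within-study
#' gradients `rho sigma_i / delta_i` at each value. Used when the
#' within-study correlations are unknown and a plausible range must be
#' scanned (e.g. negative values when a response endpoint should oppose a
#' mortality endpoint).
#'
#' @param tab a `study_table`; its `rho` column is replaced per value.
#' @param rho_values correlations to scan, each in (-1, 1).
#' @param method `"mle"`, `"adjusted"` or `"bayes"`.
#' @param options method options (see [fit_model()]).
#' @return data.frame with one row per rho value: point estimates, interval
#'   limits, tau2, the within-study gradient range and a convergence flag.
#'   The fitted objects are attached as the `"fits"` attribute.
#' @export
run_sensitivity <- function(tab, rho_values, method = c("adjusted", "mle", "bayes"),
                            options = NULL) {
  method <- match.arg(method)
  stopifnot(all(abs(rho_values) < 1))
  fits <- vector("list", length(rho_values))
  rows <- lapply(seq_along(rho_values), function(i) {
    r <- rho_values[i]
    tab_r <- tab
    tab_r$rho <- rep(r, nrow(tab))
    grad <- r * tab$se_theta / tab$se_gamma
    fit <- tryCatch(fit_model(tab_r, method, options), error = function(e) {
      stop("fit failed at rho = ", r, ": ", conditionMessage(e))
    })
    fits[[i]] <<- fit
    if (method == "bayes") {
      s <- fit$summary
      get <- function(p, col) s[s$parameter == p, col]
      data.frame(rho = r, alpha = get("alpha", "mean"),
                 alpha_lower = get("alpha", "pct_lower"),
                 alpha_upper = get("alpha", "pct_upper"),
                 beta = get("beta", "mean"),
                 beta_lower = get("beta", "pct_lower"),
                 beta_upper = get("beta", "pct_upper"),
                 tau2 = get("tau2", "mean"),
                 gradient_min = min(grad), gradient_max = max(grad),
                 converged = TRUE)
    } else {
      data.frame(rho = r, alpha = fit$alpha,
                 alpha_lower = fit$ci$alpha[[1L]], alpha_upper = fit$ci$alpha[[2L]],
                 beta = fit$beta,
                 beta_lower = fit$ci$beta[[1L]], beta_upper = fit$ci$beta[[2L]],
                 tau2 = fit$tau2,
                 gradient_min = min(grad), gradient_max = max(grad),
                 converged = fit$converged)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  out
}

#' Generate a synthetic example-shaped fixture
#'
#' Writes (or returns) a synthetic study table generated from the model
#' itself, shaped like the package's two motivating oncology use cases:
#' `"example1_like"` emulates a small PFS/OS review (6 studies, shared
#' positive within-study correlation 0.513, moderate standard errors,
#' between-study gradient 0.8, tau2 = 0); `"example2_like"` emulates a
#' large response-rate/OS review (42 studies, negative correlation -0.5,
#' between-study gradient -0.2, tau2 = 0.005); `"scenario"` draws from the
#' simulation grid's central cell (n = 20, beta = 0.4, rho = 0.4,
#' tau2 = 0.5, alpha = 0). These are synthetic stand-ins, not the published
#' datasets.
#'
#' @param kind one of `"example1_like"`, `"example2_like"`, `"scenario"`.
#' @param seed integer seed; output is byte-identical given it.
#' @param path optional CSV path to write via [write_study_table()].
#' @return the generated `study_table` (invisibly if `path` is given).
#' @export
make_fixture <- function(kind = c("example1_like", "example2_like", "scenario"),
                         seed = 1L, path = NULL) {
  kind <- match.arg(kind)
  set.seed(seed)
  tab <- switch(kind,
    example1_like = {
      n <- 6L
      delta <- stats::runif(n, 0.08, 0.25)
      sigma <- delta * stats::runif(n, 0.9, 1.2)
      rho <- 0.513
      gammas <- stats::runif(n, -0.7, 0.1)
      sim_from_model(0.1, 0.8, 0, gammas, sigma, delta, rho)
    },
    example2_like = {
      n <- 42L
      delta <- stats::runif(n, 0.15, 0.5)
      sigma <- delta * stats::runif(n, 0.46, 0.73)
      rho <- -0.5
      gammas <- stats::runif(n, -0.2, 1.2)
      sim_from_model(-0.09, -0.2, 0.005, gammas, sigma, delta, rho)
    },
    scenario = {
      sc <- list(alpha = 0, beta = 0.4, tau2 = 0.5, rho = 0.4,
                 n_studies = 20L, seed = seed, scenario_id = 0L)
      simulate_dataset(sc, 1L)$table
    })
  if (!is.null(path)) {
    write_study_table(tab, path)
    return(invisible(tab))
  }
  tab
}

# Draw (theta_hat, gamma_hat) from the marginal model given truth.
sim_from_model <- function(alpha, beta, tau2, gammas, sigma, delta, rho) {
  n <- length(gammas)
  gamma_hat <- gammas + delta * stats::rnorm(n)
  v2 <- sigma^2 * (1 - rho^2)
  theta_hat <- alpha + beta * gammas + (rho * sigma / delta) * (gamma_hat - gammas) +
    sqrt(v2 + tau2) * stats::rnorm(n)
  study_table(theta_hat, sigma, gamma_hat, delta, rho)
}
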