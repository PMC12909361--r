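#' Absolute percentage error
#'
#' `100 * |true - est| / |true|`.
#'
#' @param true True value, nonzero.
#' @param est Estimated value.
#' @return APE in percent.
#' @export
ape <- function(true, est) {
  if (any(true == 0)) stop("APE undefined for a true value of 0")
  100 * abs(true - est) / abs(true)
}

#' Mean absolute percentage error over a parameter set
#'
#' Arithmetic mean of per-parameter APEs.
#'
#' @param true Vector of true values.
#' @param est Vector of estimates (matched positions).
#' @return MAPE in percent.
#' @export
mape <- function(true, est) {
  if (length(true) == 0) stop("empty parameter set")
  if (length(true) != length(est)) stop("length mismatch")
  mean(ape(true, est))
}

#' Compare two population parameter distributions by sampling
#'
#' Draws `n` multivariate log-normal samples from each distribution and
#' returns the paired sample sets plus summary quantiles per parameter,
#' ready for density plotting or distance computation.
#'
#' @param mu_true,omega_true Log-scale mean vector and covariance of the
#'   reference distribution.
#' @param mu_est,omega_est Same for the estimated distribution.
#' @param n Samples per distribution (default `1e5`).
#' @param names Optional parameter names.
#' @return List with matrices `samples_true`, `samples_est` (`n x p`) and
#'   data frame `quantiles`.
#' @export
compare_distributions <- function(mu_true, omega_true, mu_est, omega_est,
                                  n = 1e5, names = NULL) {
  p <- length(mu_true)
  if (length(mu_est) != p) stop("dimension mismatch")
  draw <- function(mu, omega) {
    L <- t(chol(as.matrix(omega) + diag(1e-14, p)))
    exp(sweep(matrix(stats::rnorm(n * p), n, p) %*% t(L), 2, mu, "+"))
  }
  st <- draw(mu_true, omega_true)
  se <- draw(mu_est, omega_est)
  if (!is.null(names)) colnames(st) <- colnames(se) <- names
  qs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  quant <- do.call(rbind, lapply(seq_len(p), function(k) {
    data.frame(parameter = if (is.null(names)) k else names[k],
               quantile = qs,
               true = stats::quantile(st[, k], qs, names = FALSE),
               est = stats::quantile(se[, k], qs, names = FALSE))
  }))
  list(samples_true = st, samples_est = se, quantiles = quant)
}

#' Monte-Carlo prediction intervals for a fitted population model
#'
#' Simulates `n_draws` virtual subjects from the fitted parameter
#' distribution, solves the PK system per draw, applies measurement error
#' (`"proportional"`: `C * (1 + e)`, `e ~ N(0, error_sd^2)`, the default;
#' `"lognormal"`: `C * exp(e)`), and summarises per time point with the
#' median and the central 95% empirical quantiles (type-7 interpolation).
#'
#' @param model `"onecomp_iv_bolus"` or `"mpbpk_mab"`.
#' @param fitted Named list of fitted quantities. For the one-compartment
#'   model: `Vd_mean`, `Vd_sd`, `ke_mean`, `ke_sd` (linear scale; optional
#'   log-scale correlation `rho`) and `dose`. For the mPBPK model:
#'   `CLp_mean`, `CLp_sd`, `sigma1`, `sigma2`, plus optionally
#'   `weight_range` (default 50-75 kg), `dose_per_kg` (default 1),
#'   `T_inf` (default 1.5 h).
#' @param schedule Times (hours) at which to report the band.
#' @param n_draws Number of simulated subjects (default 1000).
#' @param error_sd Measurement-error SD (default 0.1).
#' @param error_model `"proportional"` or `"lognormal"`.
#' @param ref Reference physiology for the mPBPK model.
#' @return Data frame of class `prediction_band` with columns `time`,
#'   `lower`, `median`, `upper`.
#' @export
mc_prediction_intervals <- function(model, fitted, schedule, n_draws = 1000,
                                    error_sd = 0.1,
                                    error_model = c("proportional", "lognormal"),
                                    ref = reference_physiology()) {
  error_model <- match.arg(error_model)
  Tn <- length(schedule)
  sims <- matrix(0, n_draws, Tn)
  if (model == "onecomp_iv_bolus") {
    rho <- if (is.null(fitted$rho)) 0 else fitted$rho
    lv <- linear_to_log_moments(fitted$Vd_mean, fitted$Vd_sd^2)
    lk <- linear_to_log_moments(fitted$ke_mean, fitted$ke_sd^2)
    omega <- matrix(c(lv$var_log,
                      rho * sqrt(lv$var_log * lk$var_log),
                      rho * sqrt(lv$var_log * lk$var_log),
                      lk$var_log), 2, 2)
    L <- t(chol(omega + diag(1e-14, 2)))
    z <- matrix(stats::rnorm(2 * n_draws), n_draws, 2)
    draws <- exp(sweep(z %*% t(L), 2, c(lv$mu_log, lk$mu_log), "+"))
    for (i in seq_len(n_draws)) {
      p <- onecomp_params(draws[i, 1], draws[i, 2], fitted$dose)
      sims[i, ] <- onecomp_closed_form(schedule, p)
    }
  } else if (model == "mpbpk_mab") {
    wr <- if (is.null(fitted$weight_range)) c(50, 75) else fitted$weight_range
    dpk <- if (is.null(fitted$dose_per_kg)) 1 else fitted$dose_per_kg
    Tinf <- if (is.null(fitted$T_inf)) 1.5 else fitted$T_inf
    lc <- linear_to_log_moments(fitted$CLp_mean, fitted$CLp_sd^2)
    clp <- exp(stats::rnorm(n_draws, lc$mu_log, sqrt(lc$var_log)))
    bw <- stats::runif(n_draws, wr[1], wr[2])
    for (i in seq_len(n_draws)) {
      phys <- scale_physiology(bw[i], ref)
      est <- mpbpk_estimands(clp[i], fitted$sigma1, fitted$sigma2)
      inf <- infusion_schedule(dpk * bw[i], Tinf)
      sims[i, ] <- mpbpk_solve(schedule, phys, est, inf)[, "plasma"]
    }
  } else {
    stop("unknown model '", model, "'")
  }
  e <- matrix(stats::rnorm(n_draws * Tn, 0, error_sd), n_draws, Tn)
  sims <- if (error_model == "proportional") sims * (1 + e) else sims * exp(e)
  band <- data.frame(
    time = schedule,
    lower = apply(sims, 2, stats::quantile, 0.025, names = FALSE),
    median = apply(sims, 2, stats::quantile, 0.5, names = FALSE),
    upper = apply(sims, 2, stats::quantile, 0.975, names = FALSE)
  )
  class(band) <- c("prediction_band", "data.frame")
  band
}
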