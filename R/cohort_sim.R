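#' Population specification for virtual-cohort simulation
#'
#' Each ODE parameter gets a linear-scale mean and coefficient of
#' variation; between-parameter dependence is a correlation matrix on the
#' log scale; measurement noise is a log-scale residual SD.
#'
#' @param means Named numeric vector of linear-scale parameter means.
#' @param cvs Named numeric vector of CVs (same names), > 0.
#' @param corr Log-scale correlation matrix (identity by default).
#' @param sigma Residual log-scale SD, >= 0.
#' @param n_subjects Cohort size, >= 2.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(means, cvs, corr = diag(length(means)),
                            sigma = 0.1, n_subjects = 30L) {
  p <- length(means)
  stopifnot(length(cvs) == p, all(cvs > 0), all(means > 0),
            all(dim(corr) == c(p, p)), n_subjects >= 2, sigma >= 0)
  if (max(abs(corr - t(corr))) > 1e-12 || any(abs(diag(corr) - 1) > 1e-12)) {
    stop("corr must be symmetric with unit diagonal")
  }
  if (min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    stop("corr must be positive semidefinite")
  }
  structure(list(means = means, cvs = cvs, corr = corr, sigma = sigma,
                 n_subjects = as.integer(n_subjects)),
            class = "population_spec")
}

# Log-scale (mu, Omega) implied by a population_spec.
population_log_params <- function(spec) {
  lm <- linear_to_log_moments(spec$means, (spec$cvs * spec$means)^2)
  sds <- sqrt(lm$var_log)
  omega <- spec$corr * tcrossprod(sds)
  list(mu = lm$mu_log, omega = omega)
}

#' Sample individual parameters from the population distribution
#'
#' Converts per-parameter (mean, CV) to log-scale parameters via
#' [linear_to_log_moments()], builds the log-scale covariance from the
#' stated correlation, and draws jointly multivariate log-normal
#' individual parameter vectors.
#'
#' @param spec A [population_spec()].
#' @param n Number of subjects (defaults to `spec$n_subjects`).
#' @return `n x p` matrix of positive parameter draws, columns named.
#' @export
sample_parameters <- function(spec, n = spec$n_subjects) {
  lp <- population_log_params(spec)
  p <- length(lp$mu)
  L <- t(chol(lp$omega + diag(1e-14, p)))
  z <- matrix(stats::rnorm(n * p), n, p)
  draws <- exp(sweep(z %*% t(L), 2, lp$mu, "+"))
  colnames(draws) <- names(spec$means)
  draws
}

#' Simulate observed concentration profiles for a cohort
#'
#' Evaluates the one-compartment closed form per subject at the schedule
#' times (exact, the default for that model) or numerically integrates a
#' registered model, then applies multiplicative log-normal measurement
#' noise `C_obs = C_true * exp(eps)`, `eps ~ N(0, sigma^2)`.
#'
#' @param draws `n x p` parameter matrix from [sample_parameters()] with
#'   columns `Vd` and `ke`.
#' @param schedule Observation times (hours), strictly increasing, >= 0.
#' @param dose Bolus dose (mg).
#' @param sigma Residual log-scale SD.
#' @param eps Optional pre-generated `n x length(schedule)` matrix of
#'   residual errors (frozen-noise mode, e.g. to reuse identical noise
#'   across simulation scenarios); drawn fresh when omitted.
#' @return An object of class `cohort_data`: list with `times`, `true`,
#'   `observed` (both `n x T`), `mask` (logical `n x T`, `TRUE` =
#'   available), `params`, `sigma`, `dose`.
#' @export
simulate_observations <- function(draws, schedule, dose, sigma, eps = NULL) {
  if (is.unsorted(schedule, strictly = TRUE) || any(schedule < 0)) {
    stop("schedule must be strictly increasing and nonnegative")
  }
  n <- nrow(draws); Tn <- length(schedule)
  true <- matrix(0, n, Tn)
  for (k in seq_len(n)) {
    pk <- onecomp_params(draws[k, "Vd"], draws[k, "ke"], dose)
    true[k, ] <- onecomp_closed_form(schedule, pk)
  }
  if (is.null(eps)) eps <- matrix(stats::rnorm(n * Tn, 0, sigma), n, Tn)
  if (!all(dim(eps) == c(n, Tn))) stop("eps dimension mismatch")
  structure(list(times = schedule, true = true, observed = true * exp(eps),
                 mask = matrix(TRUE, n, Tn), params = draws,
                 sigma = sigma, dose = dose),
            class = "cohort_data")
}

#' Aggregate a cohort into per-timepoint summary statistics
#'
#' Per time point, computes the mean and the unbiased (`n - 1`) variance of
#' the unmasked observations, recording the contributing count. Time points
#' with fewer than two unmasked observations are dropped with a warning.
#'
#' @param cohort A `cohort_data` object.
#' @return A `data.frame` of class `aggregated_series` with columns
#'   `time`, `mean`, `var`, `sd`, `n`.
#' @export
aggregate_cohort <- function(cohort) {
  Tn <- length(cohort$times)
  out <- data.frame(time = cohort$times, mean = NA_real_, var = NA_real_,
                    sd = NA_real_, n = NA_integer_)
  for (j in seq_len(Tn)) {
    vals <- cohort$observed[cohort$mask[, j], j]
    out$n[j] <- length(vals)
    if (length(vals) >= 2) {
      out$mean[j] <- mean(vals)
      out$var[j] <- stats::var(vals)
      out$sd[j] <- sqrt(out$var[j])
    }
  }
  dropped <- out$n < 2
  if (any(dropped)) {
    warning(sum(dropped), " time point(s) dropped: fewer than 2 observations")
    out <- out[!dropped, , drop = FALSE]
  }
  class(out) <- c("aggregated_series", "data.frame")
  out
}

#' Randomly mask observations to emulate incomplete sampling
#'
#' Marks a uniformly random fraction of the subject-by-time grid as
#' missing. Reproducible under the current RNG stream.
#'
#' @param cohort A `cohort_data` object.
#' @param fraction Proportion masked, in `[0, 1)`.
#' @return The cohort with an updated `mask`.
#' @export
mask_missing <- function(cohort, fraction) {
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  n_cells <- length(cohort$mask)
  n_mask <- round(fraction * n_cells)
  mask <- cohort$mask
  if (n_mask > 0) mask[sample.int(n_cells, n_mask)] <- FALSE
  counts <- colSums(mask)
  if (any(counts < 2)) {
    warning("some time points retain fewer than 2 observations; ",
            "aggregate_cohort() will drop them")
  }
  cohort$mask <- mask
  cohort
}

#' Simulate the one-compartment IV bolus study
#'
#' Generates the default simulation study: 30 virtual subjects receiving a
#' 300 mg bolus, sampled at 0.5, 1, 2, 6, 12 and 24 h; `Vd` log-normal
#' with mean 15 L and 10% CV; `ke` log-normal with mean `log(2) / 6` 1/h
#' (6 h mean half-life) and 40% CV; log-scale correlation `rho` between
#' the two (0 by default); residual log-scale SD 0.1.
#'
#' @param n_subjects Cohort size.
#' @param dose Bolus dose (mg).
#' @param schedule Observation times (hours).
#' @param vd_mean,vd_cv `Vd` linear-scale mean (L) and CV.
#' @param t_half Mean elimination half-life (h); `ke` mean is `log(2) / t_half`.
#' @param ke_cv `ke` CV.
#' @param rho Log-scale correlation between `Vd` and `ke`.
#' @param sigma Residual log-scale SD.
#' @param missing_fraction Optional fraction of observations masked before
#'   aggregation.
#' @param eps Optional frozen residual-error matrix (see
#'   [simulate_observations()]).
#' @return List with `cohort`, `data` (the [aggregate_cohort()] output),
#'   `truth` (named vector of the five generating distributional
#'   parameters: `mu_ke`, `sd_ke`, `mu_Vd`, `sd_Vd`, `sigma`) and `spec`.
#' @export
simulate_onecomp_study <- function(n_subjects = 30L, dose = 300,
                                   schedule = c(0.5, 1, 2, 6, 12, 24),
                                   vd_mean = 15, vd_cv = 0.1,
                                   t_half = 6, ke_cv = 0.4,
                                   rho = 0, sigma = 0.1,
                                   missing_fraction = 0, eps = NULL) {
  ke_mean <- log(2) / t_half
  spec <- population_spec(
    means = c(Vd = vd_mean, ke = ke_mean),
    cvs = c(Vd = vd_cv, ke = ke_cv),
    corr = matrix(c(1, rho, rho, 1), 2, 2),
    sigma = sigma, n_subjects = n_subjects
  )
  draws <- sample_parameters(spec)
  cohort <- simulate_observations(draws, schedule, dose, sigma, eps = eps)
  if (missing_fraction > 0) cohort <- mask_missing(cohort, missing_fraction)
  truth <- c(mu_ke = ke_mean, sd_ke = ke_cv * ke_mean,
             mu_Vd = vd_mean, sd_Vd = vd_cv * vd_mean, sigma = sigma)
  list(cohort = cohort, data = aggregate_cohort(cohort), truth = truth,
       spec = spec)
}

#' Default aggregated-sampling schedule for the mAb study
#'
#' Fifteen time points spanning 0.75 h (mid-infusion) to 99 days,
#' mimicking a dense early phase followed by long-term kinetics. The exact
#' times of the original study are not published, so these defaults are
#' synthetic and overridable.
#'
#' @return Numeric vector of 15 times in hours.
#' @export
mab_default_schedule <- function() {
  c(0.75, 1.75, 2.5, 3.5, 5.5, 9.5, 24, 72, 168, 336, 672, 1176, 1680,
    2040, 2376)
}

#' Simulate a body-weight-scaled mAb virtual cohort (mPBPK model)
#'
#' Per subject: body weight uniform on `weight_range`, dose
#' `dose_per_kg * weight` infused over `T_inf`, physiology scaled linearly
#' to the weight, clearance drawn log-normally, the minimal PBPK system
#' solved exactly (linear system, matrix exponential), and multiplicative
#' log-normal measurement noise applied to the plasma profile.
#'
#' @param n_subjects Cohort size.
#' @param weight_range Body-weight interval in kg (default 50-75).
#' @param dose_per_kg Dose in mg/kg (default 1).
#' @param clp_mean,clp_cv Linear-scale mean (L/h) and CV of `CLp`.
#' @param sigma1,sigma2 Vascular reflection coefficients (tight, leaky),
#'   with `sigma1 > sigma2`.
#' @param sigma Residual log-scale SD.
#' @param schedule Observation times (hours).
#' @param T_inf Infusion duration (hours).
#' @param ref Reference physiology (see [reference_physiology()]).
#' @return List with `cohort` (class `cohort_data`, plus `weights` and
#'   `clp` vectors) and `data` (the aggregated series).
#' @export
simulate_mab_cohort <- function(n_subjects = 49L, weight_range = c(50, 75),
                                dose_per_kg = 1, clp_mean = 0.0115,
                                clp_cv = 0.35, sigma1 = 0.84, sigma2 = 0.75,
                                sigma = 0.1, schedule = mab_default_schedule(),
                                T_inf = 1.5, ref = reference_physiology()) {
  stopifnot(n_subjects >= 2, sigma1 > sigma2, sigma2 > 0, sigma1 < 1)
  bw <- stats::runif(n_subjects, weight_range[1], weight_range[2])
  lm <- linear_to_log_moments(clp_mean, (clp_cv * clp_mean)^2)
  clp <- exp(stats::rnorm(n_subjects, lm$mu_log, sqrt(lm$var_log)))
  Tn <- length(schedule)
  true <- matrix(0, n_subjects, Tn)
  for (k in seq_len(n_subjects)) {
    phys <- scale_physiology(bw[k], ref)
    est <- mpbpk_estimands(clp[k], sigma1, sigma2)
    inf <- infusion_schedule(dose_per_kg * bw[k], T_inf)
    true[k, ] <- mpbpk_solve(schedule, phys, est, inf)[, "plasma"]
  }
  eps <- matrix(stats::rnorm(n_subjects * Tn, 0, sigma), n_subjects, Tn)
  cohort <- structure(list(times = schedule, true = true,
                           observed = true * exp(eps),
                           mask = matrix(TRUE, n_subjects, Tn),
                           params = cbind(CLp = clp, bw = bw),
                           weights = bw, clp = clp, sigma = sigma,
                           T_inf = T_inf, dose_per_kg = dose_per_kg),
                      class = "cohort_data")
  list(cohort = cohort, data = aggregate_cohort(cohort))
}
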