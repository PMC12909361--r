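#' Convert linear-scale moments to log-normal log-scale parameters
#'
#' For a log-normal variable with linear-scale mean `m > 0` and variance
#' `v >= 0`, the log-scale parameters are
#' `mu_log = log(m^2 / sqrt(m^2 + v))` and `var_log = log(1 + v / m^2)`.
#' Exact inverse of [log_to_linear_moments()].
#'
#' @param mean Linear-scale mean(s), > 0.
#' @param variance Linear-scale variance(s), >= 0.
#' @return List with `mu_log` and `var_log`.
#' @export
linear_to_log_moments <- function(mean, variance) {
  if (any(!is.finite(mean)) || any(mean <= 0)) {
    stop("linear-scale mean must be positive to parameterise a log-normal")
  }
  if (any(variance < 0)) stop("variance must be nonnegative")
  q <- log1p(variance / mean^2)
  list(mu_log = log(mean) - q / 2, var_log = q)
}

#' Convert log-normal log-scale parameters to linear-scale moments
#'
#' `mean = exp(mu_log + var_log / 2)`;
#' `variance = (exp(var_log) - 1) * exp(2 mu_log + var_log)`.
#'
#' @param mu_log Log-scale mean(s).
#' @param var_log Log-scale variance(s), >= 0.
#' @return List with `mean` and `variance`.
#' @export
log_to_linear_moments <- function(mu_log, var_log) {
  if (any(var_log < 0)) stop("var_log must be nonnegative")
  m <- exp(mu_log + var_log / 2)
  list(mean = m, variance = expm1(var_log) * m^2)
}

#' Project a symmetric matrix to the nearest positive semidefinite matrix
#'
#' Symmetric eigenvalue clipping: eigenvalues below `jitter` are raised to
#' `jitter`. Leaves matrices whose smallest eigenvalue already exceeds
#' `jitter` untouched.
#'
#' @param S Symmetric matrix.
#' @param jitter Eigenvalue floor (default `1e-6`).
#' @return Repaired symmetric matrix with smallest eigenvalue >= `jitter`.
#' @export
nearest_psd <- function(S, jitter = 1e-6) {
  S <- (S + t(S)) / 2
  eg <- eigen(S, symmetric = TRUE)
  if (min(eg$values) >= jitter) return(S)
  V <- eg$vectors
  S2 <- V %*% (pmax(eg$values, jitter) * t(V))
  (S2 + t(S2)) / 2
}

#' Assemble the joint log-scale distribution over concentration and parameters
#'
#' Builds, for one time point, the mean vector and covariance matrix of the
#' joint multivariate normal over `(log C, log eta_1, ..., log eta_p)`. The
#' first entry carries the log-scale moments of the surrogate's predicted
#' concentration mean/variance (via [linear_to_log_moments()]); the
#' parameter block carries the (time-invariant) population log-scale mean
#' and covariance; the concentration-parameter cross covariances come from
#' the trainable correlation vector `cross_corr`. If the implied matrix is
#' not positive semidefinite it is repaired with [nearest_psd()].
#'
#' @param nn_mean,nn_variance Surrogate-predicted linear-scale mean and
#'   variance of the observed concentration at this time point.
#' @param mu_eta Log-scale mean vector of the ODE parameters.
#' @param omega_eta Log-scale covariance matrix of the ODE parameters.
#' @param cross_corr Correlations between `log C` and each `log eta`,
#'   in `[-1, 1]`; defaults to zeros.
#' @param jitter Eigenvalue floor used by the PSD repair.
#' @return List with `mu_prime` (length `p + 1`) and `omega_prime`
#'   (`(p+1) x (p+1)`).
#' @export
assemble_joint <- function(nn_mean, nn_variance, mu_eta, omega_eta,
                           cross_corr = rep(0, length(mu_eta)),
                           jitter = 1e-6) {
  p <- length(mu_eta)
  if (!all(dim(omega_eta) == c(p, p))) stop("omega_eta dimension mismatch")
  if (length(cross_corr) != p) stop("cross_corr dimension mismatch")
  lm <- linear_to_log_moments(nn_mean, max(nn_variance, 1e-12))
  d <- p + 1L
  mu <- c(lm$mu_log, mu_eta)
  omega <- matrix(0, d, d)
  omega[1, 1] <- lm$var_log
  omega[2:d, 2:d] <- omega_eta
  sd_c <- sqrt(lm$var_log)
  sd_eta <- sqrt(diag(omega_eta))
  omega[1, 2:d] <- omega[2:d, 1] <- cross_corr * sd_c * sd_eta
  ev <- eigen((omega + t(omega)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < jitter) omega <- nearest_psd(omega, jitter)
  list(mu_prime = mu, omega_prime = omega)
}

#' Draw reparameterised samples from the joint log-normal
#'
#' Samples `exp(mu_prime + chol(omega_prime) z)` with `z` standard normal,
#' so draws are differentiable functions of the distributional parameters
#' (reparameterisation trick) and deterministic given the RNG state. The
#' first column is the observed-scale (noisy) concentration; remaining
#' columns are the ODE parameter draws.
#'
#' @param jp Joint parameters from [assemble_joint()].
#' @param n Number of draws, >= 2.
#' @param z Optional `(n x d)` matrix of standard-normal innovations; drawn
#'   from the current RNG stream when omitted.
#' @return `(n x d)` matrix of positive draws.
#' @export
draw_joint <- function(jp, n, z = NULL) {
  d <- length(jp$mu_prime)
  if (n < 2) stop("n must be >= 2 (downstream variance estimator)")
  if (is.null(z)) z <- matrix(stats::rnorm(n * d), n, d)
  omega <- jp$omega_prime
  # guard exact-zero variance blocks: chol of PSD (not PD) matrices
  L <- tryCatch(t(chol(omega)), error = function(e) {
    t(chol(nearest_psd(omega, 1e-12) + diag(1e-12, d)))
  })
  exp(sweep(z %*% t(L), 2, jp$mu_prime, "+"))
}

#' Denoise sampled observed concentrations
#'
#' The measurement model is `C = C_true * exp(eps)`, `eps ~ N(0, sigma^2)`.
#' Denoising inverts it stochastically: each draw is divided by a freshly
#' sampled `exp(eps)`.
#'
#' @param c_noisy Positive draws of the observed concentration.
#' @param sigma Residual log-scale SD, >= 0.
#' @param eps Optional pre-drawn `N(0, sigma^2)` errors (same shape as
#'   `c_noisy`); sampled from the current RNG stream when omitted.
#' @return Draws of the true (noise-free) concentration.
#' @export
denoise_samples <- function(c_noisy, sigma, eps = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (is.null(eps)) eps <- stats::rnorm(length(c_noisy), 0, sigma)
  c_noisy * exp(-eps)
}

#' Sample-based derivative of the mean concentration
#'
#' Arithmetic mean of the per-sample ODE right-hand-side evaluations: the
#' Monte-Carlo estimate of `d E[C_true] / dt`.
#'
#' @param derivatives Per-sample RHS derivatives (vector).
#' @return Scalar derivative estimate.
#' @export
estimate_mean_derivative <- function(derivatives) {
  if (length(derivatives) < 1) stop("empty sample batch")
  mean(derivatives)
}

#' Sample-based derivative of the concentration variance
#'
#' `(2 / (N - 1)) * sum_i (C_i - mean(C)) * (dC_i - mean(dC))`: the
#' unbiased-variance analogue of the product rule, pairing each denoised
#' concentration draw with its RHS derivative.
#'
#' @param c_true Denoised concentration draws.
#' @param derivatives Matching per-sample RHS derivatives.
#' @return Scalar derivative estimate.
#' @export
estimate_var_derivative <- function(c_true, derivatives) {
  n <- length(c_true)
  if (n < 2) stop("need at least 2 samples for the variance derivative")
  if (length(derivatives) != n) stop("length mismatch")
  2 / (n - 1) * sum((c_true - mean(c_true)) *
                      (derivatives - mean(derivatives)))
}

#' Reconstruct the derivative of the observed (noisy) mean
#'
#' Under the multiplicative log-normal error model the observed mean is
#' `E[C] = E[C_true] * exp(sigma^2 / 2)`, so its derivative is the true-mean
#' derivative scaled by `exp(sigma^2 / 2)`.
#'
#' @param d_mean_true Derivative of the true mean.
#' @param sigma Residual log-scale SD.
#' @return Derivative of the observed mean.
#' @export
noisy_mean_derivative <- function(d_mean_true, sigma) {
  exp(sigma^2 / 2) * d_mean_true
}

#' Reconstruct the derivative of the observed (noisy) variance
#'
#' From `Var(C) = e^(2 sigma^2) Var(C_true) + E(C_true)^2 e^(sigma^2)
#' (e^(sigma^2) - 1)`, the observed-variance derivative is
#' `e^(sigma^2) (2 E(C_true) dE(C_true)/dt (e^(sigma^2) - 1)
#' + e^(sigma^2) dVar(C_true)/dt)`.
#'
#' @param mean_true True-mean value at the evaluation time.
#' @param d_mean_true Derivative of the true mean.
#' @param d_var_true Derivative of the true variance.
#' @param sigma Residual log-scale SD.
#' @return Derivative of the observed variance.
#' @export
noisy_var_derivative <- function(mean_true, d_mean_true, d_var_true, sigma) {
  B <- exp(sigma^2)
  B * (2 * mean_true * d_mean_true * (B - 1) + B * d_var_true)
}

#' Convert a variance derivative to a standard-deviation derivative
#'
#' Chain rule `dSD/dt = dVar/dt / (2 SD)` with the surrogate-predicted SD in
#' the denominator; the SD is floored to keep the division stable.
#'
#' @param d_var Derivative of the variance.
#' @param sd_hat Surrogate-predicted SD, > 0.
#' @param floor Lower clamp for `sd_hat` (default `1e-8`).
#' @return Derivative of the SD.
#' @export
var_to_sd_derivative <- function(d_var, sd_hat, floor = 1e-8) {
  if (any(sd_hat <= floor)) {
    warning("sd_hat at or below floor; clamped")
    sd_hat <- pmax(sd_hat, floor)
  }
  d_var / (2 * sd_hat)
}
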