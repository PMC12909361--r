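test_that("linear/log moment transforms are exact inverses", {
  lm0 <- linear_to_log_moments(1, 0)
  expect_equal(lm0$mu_log, 0)
  expect_equal(lm0$var_log, 0)
  expect_equal(log_to_linear_moments(0, 0), list(mean = 1, variance = 0))
  set.seed(1)
  for (i in 1:200) {
    m <- runif(1, 1e-3, 100)
    v <- runif(1, 0, 50)
    lm <- linear_to_log_moments(m, v)
    back <- log_to_linear_moments(lm$mu_log, lm$var_log)
    expect_equal(back$mean, m, tolerance = 1e-12)
    expect_equal(back$variance, v, tolerance = 1e-11)
  }
  expect_error(linear_to_log_moments(-1, 1), "positive")
  expect_equal(log_to_linear_moments(log(20) - 0.005, 0.01)$mean, 20,
               tolerance = 1e-12)
})

test_that("log-scale parameters reproduce log-normal sample moments", {
  lm <- linear_to_log_moments(20, 4)
  expect_equal(lm$mu_log, 2.9905, tolerance = 1e-4)
  expect_equal(lm$var_log, 0.009950, tolerance = 1e-4)
  set.seed(9)
  x <- exp(rnorm(1e6, lm$mu_log, sqrt(lm$var_log)))
  expect_equal(mean(x), 20, tolerance = 3 * sd(x) / sqrt(1e6) / 20)
  expect_equal(var(x), 4, tolerance = 0.05)
})

test_that("nearest_psd clips eigenvalues and leaves PSD matrices alone", {
  S_ok <- diag(c(2, 1))
  expect_equal(nearest_psd(S_ok), S_ok)
  S_bad <- matrix(c(1, 0.99, 0.8, 0.99, 1, -0.5, 0.8, -0.5, 1), 3, 3)
  expect_lt(min(eigen(S_bad, symmetric = TRUE)$values), 0)
  rep_ <- nearest_psd(S_bad, jitter = 1e-6)
  expect_gte(min(eigen(rep_, symmetric = TRUE)$values), 1e-6 - 1e-12)
})

test_that("assemble_joint builds the documented block structure", {
  omega_eta <- matrix(c(0.01, 0.002, 0.002, 0.15), 2, 2)
  jp0 <- assemble_joint(20, 4, c(2.7, -2.2), omega_eta)
  expect_equal(jp0$omega_prime[2:3, 2:3], omega_eta)
  expect_equal(jp0$omega_prime[1, 2:3], c(0, 0))
  lm <- linear_to_log_moments(20, 4)
  expect_equal(jp0$mu_prime[1], lm$mu_log)
  expect_equal(jp0$omega_prime[1, 1], lm$var_log)
  # cross-correlations fill the off-diagonal block
  jp <- assemble_joint(20, 4, c(2.7, -2.2), omega_eta,
                       cross_corr = c(0.3, -0.5))
  expect_equal(jp$omega_prime[1, 2],
               0.3 * sqrt(lm$var_log) * sqrt(0.01))
  expect_equal(jp$omega_prime[1, 3],
               -0.5 * sqrt(lm$var_log) * sqrt(0.15))
  expect_error(assemble_joint(20, 4, c(2.7, -2.2), omega_eta,
                              cross_corr = 0.3), "dimension")
})

test_that("assemble_joint repairs a non-PSD assembly", {
  # strong opposing cross-correlations with an anticorrelated parameter
  # block cannot come from any joint distribution
  omega_eta <- matrix(c(0.04, -0.9 * 0.2 * 0.3, -0.9 * 0.2 * 0.3, 0.09), 2, 2)
  jp <- assemble_joint(10, 30, c(0, 0), omega_eta,
                       cross_corr = c(0.95, 0.95))
  ev <- eigen(jp$omega_prime, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 1e-6 - 1e-12)
})

test_that("reparameterised joint sampling is exact in its moments", {
  jp <- list(mu_prime = c(3, 0.5), omega_prime = matrix(0, 2, 2))
  draws <- draw_joint(jp, 10)
  expect_true(all(abs(draws[, 1] - exp(3)) < 1e-4))
  expect_true(all(abs(draws[, 2] - exp(0.5)) < 1e-4))
  expect_error(draw_joint(jp, 1), ">= 2")
  # determinism under seed
  omega <- matrix(c(0.05, 0.01, 0.01, 0.08), 2, 2)
  jp2 <- list(mu_prime = c(1, -1), omega_prime = omega)
  set.seed(5); a <- draw_joint(jp2, 100)
  set.seed(5); b <- draw_joint(jp2, 100)
  expect_identical(a, b)
  # Monte-Carlo consistency of log-scale moments
  set.seed(6)
  big <- log(draw_joint(jp2, 2e5))
  expect_equal(colMeans(big), c(1, -1), tolerance = 0.005)
  expect_equal(cov(big), omega, tolerance = 0.005)
})

test_that("stochastic denoising inverts the error model", {
  x <- c(1, 2, 5)
  expect_identical(denoise_samples(x, 0), x)
  expect_equal(denoise_samples(2, 0.3, eps = log(2)), 1)
  # mean of denoised draws is inflated by exp(sigma^2/2) relative to input
  set.seed(8)
  c_noisy <- exp(rnorm(1e6, 1, 0.2))
  ct <- denoise_samples(c_noisy, 0.25)
  expect_equal(mean(ct), mean(c_noisy) * exp(0.25^2 / 2), tolerance = 0.01)
})

test_that("sample moment-derivative estimators match hand evaluation", {
  expect_equal(estimate_mean_derivative(c(1, 2, 3)), 2)
  expect_equal(estimate_mean_derivative(rep(0.7, 9)), 0.7)
  expect_error(estimate_mean_derivative(numeric(0)), "empty")
  expect_equal(estimate_var_derivative(c(1, 3), c(0, 2)), 4)
  expect_equal(estimate_var_derivative(rep(2, 5), rep(3, 5)), 0)
  # bilinearity: negating derivatives about their mean flips the sign
  set.seed(2)
  cs <- runif(50); ds <- rnorm(50)
  v1 <- estimate_var_derivative(cs, ds)
  v2 <- estimate_var_derivative(cs, 2 * mean(ds) - ds)
  expect_equal(v2, -v1 + 2 * 0, tolerance = 1e-12)
  expect_error(estimate_var_derivative(1, 1), "2 samples")
})

test_that("mean/variance derivative estimators track the sampled joint", {
  # at one time point, compare the estimators against central finite
  # differences of the exactly-propagated sample moments (same draws)
  set.seed(12)
  n <- 2e5; D <- 300; t <- 4; h <- 1e-4
  lmv <- linear_to_log_moments(15, 1.5^2)
  lmk <- linear_to_log_moments(log(2) / 6, (0.4 * log(2) / 6)^2)
  Vd <- exp(rnorm(n, lmv$mu_log, sqrt(lmv$var_log)))
  ke <- exp(rnorm(n, lmk$mu_log, sqrt(lmk$var_log)))
  C <- D / Vd * exp(-ke * t)
  dC <- -ke * C
  fd_mean <- (mean(D / Vd * exp(-ke * (t + h))) -
                mean(D / Vd * exp(-ke * (t - h)))) / (2 * h)
  fd_var <- (var(D / Vd * exp(-ke * (t + h))) -
               var(D / Vd * exp(-ke * (t - h)))) / (2 * h)
  expect_equal(estimate_mean_derivative(dC), fd_mean, tolerance = 1e-6)
  expect_equal(estimate_var_derivative(C, dC), fd_var, tolerance = 1e-4)
})

test_that("noisy-moment reconstruction matches the exact error algebra", {
  expect_equal(noisy_mean_derivative(3, 0), 3)
  expect_equal(noisy_mean_derivative(1, 0.1), exp(0.005), tolerance = 1e-12)
  expect_equal(noisy_mean_derivative(-4, 0.2), -4 * exp(0.02),
               tolerance = 1e-12)
  expect_equal(noisy_var_derivative(5, 2, 3, 0), 3)
  expect_equal(noisy_var_derivative(5, 0, 3, 0.3), exp(2 * 0.09) * 3,
               tolerance = 1e-12)
  # symbolic check: Var[C] = e^{2s2} Var_t + E_t^2 e^{s2}(e^{s2}-1), so the
  # reconstruction must equal the derivative of that expression
  s <- 0.25
  Et <- 7; dEt <- -1.3; dVt <- 2.1
  manual <- exp(2 * s^2) * dVt + 2 * Et * dEt * exp(s^2) * (exp(s^2) - 1)
  expect_equal(noisy_var_derivative(Et, dEt, dVt, s), manual,
               tolerance = 1e-12)
})

test_that("noisy variance derivative agrees with Monte-Carlo differentiation", {
  set.seed(13)
  n <- 1e6; s <- 0.15; t <- 3; h <- 1e-3
  p <- default_onecomp_params()
  lmk <- linear_to_log_moments(log(2) / 6, (0.4 * log(2) / 6)^2)
  ke <- exp(rnorm(n, lmk$mu_log, sqrt(lmk$var_log)))
  eps <- rnorm(n, 0, s)
  varn <- function(tt) var(20 * exp(-ke * tt) * exp(eps))
  fd <- (varn(t + h) - varn(t - h)) / (2 * h)
  Ct <- 20 * exp(-ke * t)
  dCt <- -ke * Ct
  recon <- noisy_var_derivative(mean(Ct), mean(dCt),
                                estimate_var_derivative(Ct, dCt), s)
  expect_equal(recon, fd, tolerance = 0.02)
})

test_that("variance-to-SD derivative applies the chain rule with a floor", {
  expect_equal(var_to_sd_derivative(4, 1), 2)
  expect_equal(var_to_sd_derivative(0, 0.3), 0)
  # Var(t) = t^2 has SD(t) = t, so dSD = dVar / (2 t) = 1 at t = 1
  expect_equal(var_to_sd_derivative(2 * 1, 1), 1)
  expect_warning(out <- var_to_sd_derivative(1, 1e-12), "floor")
  expect_true(is.finite(out))
})
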