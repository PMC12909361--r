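test_that("total loss is the exact weighted sum of its six components", {
  comps <- list(ode_mean = 1, ode_var = 2, ic_mean = 3, ic_var = 4,
                data_mean = 5, data_var = 6)
  out <- total_loss(comps, loss_weights())
  expect_equal(out$total, 21)
  out2 <- total_loss(comps, loss_weights(ode_var = 2))
  expect_equal(out2$total, 21 + 2)
  expect_error(loss_weights(ic_mean = -1), "nonnegative")
  expect_equal(total_loss(as.list(setNames(rep(0, 6), names(loss_weights()))),
                          loss_weights())$total, 0)
})

test_that("data losses are mean squared errors excluding masked points", {
  out <- data_losses(5, 8, 3, 5)
  expect_equal(out$data_mean, 4)
  expect_equal(out$data_var, 9)
  # 3-point toy with one masked observation, recomputed by hand
  out2 <- data_losses(c(10, 6, 2), c(4, 3, 1),
                      c(9, NA, 1.5), c(3.5, NA, 0.8))
  expect_equal(out2$data_mean, ((10 - 9)^2 + (2 - 1.5)^2) / 2)
  expect_equal(out2$data_var, ((4 - 3.5)^2 + (1 - 0.8)^2) / 2)
  expect_error(data_losses(1, 1, NA, NA), "unmasked")
})

test_that("ODE losses average squared channel residuals", {
  expect_error(ode_losses(numeric(0), numeric(0), numeric(0), numeric(0)),
               "empty")
  out <- ode_losses(c(1, 2), c(0, 0), c(1, 2), c(0, 0))
  expect_equal(out$ode_mean, 0)
  # duplicating points with identical residuals leaves the loss unchanged
  a <- ode_losses(c(1, 3), c(2, 2), c(0, 2), c(1, 1))
  b <- ode_losses(rep(c(1, 3), 2), rep(c(2, 2), 2),
                  rep(c(0, 2), 2), rep(c(1, 1), 2))
  expect_equal(a, b)
})

test_that("initial-condition loss reproduces the sampled bolus summaries", {
  # degenerate Vd at 15 L, no noise: observed C0 is exactly 20 mg/L
  out <- ic_losses(20, 0, dose = 300, mu_vd_log = log(15), sd_vd_log = 0,
                   sigma = 0, n = 50)
  expect_equal(out$ic_mean, 0)
  expect_equal(out$mean0, 20)
  # sampled mean converges to the log-normal reciprocal closed form
  lmv <- linear_to_log_moments(15, 1.5^2)
  set.seed(10)
  out2 <- ic_losses(20, 4, dose = 300, mu_vd_log = lmv$mu_log,
                    sd_vd_log = sqrt(lmv$var_log), sigma = 0.1, n = 4e5)
  closed <- 300 * exp(-lmv$mu_log + lmv$var_log / 2) * exp(0.1^2 / 2)
  expect_equal(out2$mean0, closed, tolerance = 0.005)
  expect_error(ic_losses(1, 1, 300, log(15), 0.1, 0.1, n = 1), ">= 2")
})

test_that("compiled loss matches the module-composed reference loss", {
  for (kind in c("onecomp", "mpbpk")) {
    for (dn in c("joint", "stochastic")) {
      ts <- tiny_setup(kind, denoise = dn)
      draws <- dpinns:::dpinn_draw_inputs(ts$setup$cfg)
      core <- core_loss(ts, ts$par0, draws)
      ref <- dpinns:::dpinn_reference_loss(ts$par0, ts$setup$cfg, draws)
      for (nm in c("ode_mean", "ode_var", "ic_mean", "ic_var",
                   "data_mean", "data_var", "total")) {
        expect_equal(core[[nm]], ref[[nm]], tolerance = 1e-10,
                     label = paste(kind, dn, nm))
      }
    }
  }
})

test_that("analytic gradients match finite differences of the loss", {
  for (kind in c("onecomp", "mpbpk")) {
    ts <- tiny_setup(kind)
    draws <- dpinns:::dpinn_draw_inputs(ts$setup$cfg)
    g <- core_loss(ts, ts$par0, draws, want_grad = TRUE)$grad
    f <- function(p) core_loss(ts, p, draws)$total
    h <- 1e-6
    # spot-check every distributional parameter and a spread of weights
    n_par <- length(ts$par0)
    nw <- dpinns:::n_weight_params(ts$setup$net_spec)
    idx <- unique(c(round(seq(1, nw, length.out = 25)), (nw + 1):n_par))
    for (k in idx) {
      e <- rep(0, n_par); e[k] <- h
      fd <- (f(ts$par0 + e) - f(ts$par0 - e)) / (2 * h)
      expect_equal(g[k], fd, tolerance = 1e-4,
                   label = paste(kind, "par", k))
    }
  }
})

test_that("relative residual weighting preserves the loss/gradient match", {
  ts <- tiny_setup("mpbpk")
  ts$setup$cfg$relative_ode_residuals <- TRUE
  draws <- dpinns:::dpinn_draw_inputs(ts$setup$cfg)
  core <- core_loss(ts, ts$par0, draws, want_grad = TRUE)
  ref <- dpinns:::dpinn_reference_loss(ts$par0, ts$setup$cfg, draws)
  expect_equal(core$total, ref$total, tolerance = 1e-10)
  f <- function(p) core_loss(ts, p, draws)$total
  n_par <- length(ts$par0)
  for (k in (n_par - 4):n_par) {
    e <- rep(0, n_par); e[k] <- 1e-6
    fd <- (f(ts$par0 + e) - f(ts$par0 - e)) / 2e-6
    expect_equal(core$grad[k], fd, tolerance = 1e-4)
  }
})

test_that("zero-iteration training returns the initial parameters", {
  set.seed(31)
  study <- simulate_onecomp_study()
  model <- pk_model("onecomp_iv_bolus", dose = 300)
  cfg <- dpinn_config(n_collocation = 5, n_samples = 4, iterations = 0L,
                      n_ic_samples = 4)
  setup <- dpinns:::dpinn_setup(study$data, model, cfg)
  par0 <- dpinns:::dpinn_init_par(study$data, model, cfg, setup)
  fit <- train_dpinn(study$data, model, cfg, init = par0)
  expect_identical(fit$par, as.numeric(par0))
})

test_that("training is deterministic given the seed and logs a consistent total", {
  run_once <- function() {
    set.seed(77)
    study <- simulate_onecomp_study(n_subjects = 12)
    model <- pk_model("onecomp_iv_bolus", dose = 300)
    train_dpinn(study$data, model,
                dpinn_config(n_collocation = 10, n_samples = 8,
                             iterations = 150L, n_ic_samples = 8,
                             log_every = 25L))
  }
  f1 <- run_once()
  f2 <- run_once()
  expect_identical(f1$par, f2$par)
  h <- f1$history
  expect_equal(h$total,
               h$ode_mean + h$ode_var + h$ic_mean + h$ic_var +
                 h$data_mean + h$data_var,
               tolerance = 1e-12)
})

test_that("one Adam step with clipping reproduces a manual update", {
  ts <- tiny_setup("onecomp")
  clip <- 0.5
  set.seed(123)
  res <- dpinns:::.dpinn_train(ts$par0, ts$setup$cfg, 1L, 5e-4, 1, 1000L,
                               clip, 1L, FALSE)
  set.seed(123)
  draws <- dpinns:::dpinn_draw_inputs(ts$setup$cfg)
  g <- as.numeric(core_loss(ts, ts$par0, draws, want_grad = TRUE)$grad)
  gn <- sqrt(sum(g^2))
  expect_gt(gn, clip)  # the fixture really does trigger clipping
  g <- g * clip / gn
  m_hat <- (0.1 * g) / (1 - 0.9)
  v_hat <- (0.001 * g^2) / (1 - 0.999)
  manual <- ts$par0 - 5e-4 * m_hat / (sqrt(v_hat) + 1e-8)
  expect_equal(as.numeric(res$par), manual, tolerance = 1e-12)
})

test_that("case-1 estimates improve markedly over the initialisation", {
  set.seed(41)
  study <- simulate_onecomp_study()
  model <- pk_model("onecomp_iv_bolus", dose = 300)
  fit <- train_dpinn(study$data, model,
                     dpinn_config(n_collocation = 40, n_samples = 30,
                                  iterations = 4000L))
  est <- c(fit$estimates$mean[2], fit$estimates$sd[2],
           fit$estimates$mean[1], fit$estimates$sd[1], fit$sigma)
  # a short run already lands the means within 15% and halves the loss
  expect_lt(ape(study$truth[["mu_Vd"]], est[3]), 15)
  expect_lt(ape(study$truth[["mu_ke"]], est[1]), 25)
  expect_lt(tail(fit$history$total, 1), fit$history$total[1] / 10)
})
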