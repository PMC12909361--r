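test_that("one-compartment RHS implements first-order elimination", {
  expect_equal(onecomp_rhs(20, 0, onecomp_params(15, 0.1, 300)), -2)
  expect_equal(onecomp_rhs(0, 5, onecomp_params(15, 0.37, 300)), 0)
  expect_equal(onecomp_rhs(10, 1, onecomp_params(15, log(2) / 6, 300)),
               -10 * log(2) / 6, tolerance = 1e-12)
  expect_error(onecomp_rhs(NaN, 0, default_onecomp_params()), "non-finite")
})

test_that("bolus initial condition is dose over volume", {
  expect_equal(onecomp_initial(onecomp_params(15, 0.1, 300)), 20)
  expect_equal(onecomp_initial(onecomp_params(15, 0.1, 0)), 0)
  expect_equal(onecomp_initial(onecomp_params(10, 0.1, 300)), 30)
  expect_error(onecomp_params(-1, 0.1, 300), "Vd")
})

test_that("closed form matches half-life arithmetic and rejects negative time", {
  p <- default_onecomp_params()
  expect_equal(onecomp_closed_form(0, p), 20)
  expect_equal(onecomp_closed_form(6, p), 10, tolerance = 1e-12)
  expect_equal(onecomp_closed_form(24, p), 1.25, tolerance = 1e-12)
  expect_error(onecomp_closed_form(-1, p), "negative")
})

test_that("numeric integration of the elimination ODE matches the closed form", {
  p <- default_onecomp_params()
  times <- c(0, 0.5, 1, 2, 6, 12, 24)
  sol <- deSolve::lsoda(onecomp_initial(p), times,
                        function(t, y, parms) list(onecomp_rhs(y, t, p)),
                        NULL, rtol = 1e-11, atol = 1e-13)
  expect_equal(as.numeric(sol[, 2]), onecomp_closed_form(times, p),
               tolerance = 1e-8)
})

test_that("physiology scaling is linear and preserves the flow partition", {
  ref <- reference_physiology()
  at_ref <- scale_physiology(ref$ref_weight, ref)
  expect_equal(at_ref$V_plasma, ref$V_plasma)
  expect_equal(at_ref$L, ref$L)
  dbl <- scale_physiology(2 * ref$ref_weight, ref)
  expect_equal(dbl$V_tight, 2 * ref$V_tight)
  expect_equal(dbl$L2, 2 * ref$L2)
  for (w in c(43.7, 58, 70, 91.2)) {
    ph <- scale_physiology(w, ref)
    expect_equal(ph$L1 + ph$L2, ph$L, tolerance = 1e-12)
    expect_equal(ph$sigma_L, ref$sigma_L)
  }
  expect_error(scale_physiology(0, ref), "positive")
})

test_that("mPBPK RHS satisfies mass balance and the quiescent state", {
  m <- default_mpbpk()
  expect_equal(mpbpk_rhs(c(0, 0, 0, 0), 10, m$phys, m$est, m$inf),
               c(0, 0, 0, 0))
  # volume-weighted derivative sum equals input minus plasma elimination
  set.seed(7)
  vols <- with(m$phys, c(V_plasma, V_tight, V_leaky, V_lymph))
  for (i in 1:25) {
    state <- runif(4, 0, 30)
    t <- runif(1, 0, 100)
    d <- mpbpk_rhs(state, t, m$phys, m$est, m$inf)
    input <- if (t <= m$inf$T_inf) m$inf$dose / m$inf$T_inf else 0
    expect_equal(sum(vols * d), input - m$est$CLp * state[1],
                 tolerance = 1e-10)
  }
})

test_that("mPBPK RHS matches independent hand computation", {
  m <- default_mpbpk()
  d <- mpbpk_rhs(c(1, 0, 0, 0), 10, m$phys, m$est, m$inf)
  ph <- m$phys
  expect_equal(d[1], -(ph$L1 * (1 - 0.8378) + ph$L2 * (1 - 0.7529) + 0.0115) /
                 ph$V_plasma)
  expect_equal(d[2], ph$L1 * (1 - 0.8378) / ph$V_tight)
  expect_equal(d[3], ph$L2 * (1 - 0.7529) / ph$V_leaky)
  expect_equal(d[4], 0)
  expect_error(mpbpk_rhs(c(1, NA, 0, 0), 0, m$phys, m$est, m$inf), "finite")
})

test_that("total mAb amount decreases strictly after the infusion ends", {
  m <- default_mpbpk()
  times <- seq(2, 2376, length.out = 120)
  sol <- mpbpk_solve(times, m$phys, m$est, m$inf)
  vols <- with(m$phys, c(V_plasma, V_tight, V_leaky, V_lymph))
  amount <- as.numeric(sol %*% vols)
  expect_true(all(diff(amount) < 0))
})

test_that("matrix-exponential and lsoda solvers agree", {
  m <- default_mpbpk(62.5)
  times <- mab_default_schedule()
  a <- mpbpk_solve(times, m$phys, m$est, m$inf, method = "matexp")
  b <- mpbpk_solve(times, m$phys, m$est, m$inf, method = "lsoda")
  expect_equal(a, b, tolerance = 1e-7)
})

test_that("batched plasma solver reproduces the per-subject solver", {
  ref <- reference_physiology()
  set.seed(3)
  bw <- runif(4, 50, 75)
  clp <- runif(4, 0.008, 0.02)
  batch <- dpinns:::mpbpk_plasma_profiles(mab_default_schedule(), bw, clp,
                                          0.84, 0.75, ref, 1, 1.5)
  for (k in 1:4) {
    single <- mpbpk_solve(mab_default_schedule(), scale_physiology(bw[k], ref),
                          mpbpk_estimands(clp[k], 0.84, 0.75),
                          infusion_schedule(bw[k], 1.5))[, "plasma"]
    expect_equal(unname(batch[k, ]), unname(single), tolerance = 1e-10)
  }
})

test_that("reflection-coefficient transform enforces 0 < sigma2 < sigma1 < 1", {
  r <- constrain_reflection(0, 0)
  expect_equal(r$sigma1, 0.5)
  expect_equal(r$sigma2, 0.25)
  r_hi <- constrain_reflection(40, 40)
  expect_equal(r_hi$sigma1, 1, tolerance = 1e-10)
  expect_equal(r_hi$sigma2, r_hi$sigma1, tolerance = 1e-10)
  set.seed(11)
  raw1 <- rnorm(1000, 0, 4)
  raw2 <- rnorm(1000, 0, 4)
  r <- constrain_reflection(raw1, raw2)
  expect_true(all(r$sigma1 > r$sigma2))
  expect_true(all(r$sigma2 > 0 & r$sigma1 < 1))
  # monotone in each raw argument
  grid <- seq(-4, 4, length.out = 50)
  expect_true(all(diff(constrain_reflection(grid, 0.3)$sigma1) > 0))
  expect_true(all(diff(constrain_reflection(0.3, grid)$sigma2) > 0))
})

test_that("model registry dispatches and reports unknown names", {
  m1 <- pk_model("onecomp_iv_bolus", dose = 300)
  expect_s3_class(m1, "ode_model_spec")
  expect_equal(m1$rhs(20, 0, c(Vd = 15, ke = 0.1)), -2)
  expect_equal(m1$initial_condition(c(Vd = 15)), 20)
  m <- default_mpbpk()
  m2 <- pk_model("mpbpk_mab", phys = m$phys, inf = m$inf)
  expect_equal(m2$n_states, 4L)
  expect_length(m2$rhs(c(1, 0, 0, 0), 10,
                       c(CLp = 0.0115, sigma1 = 0.84, sigma2 = 0.75)), 4)
  expect_error(pk_model("two_compartment"), "onecomp_iv_bolus")
})
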