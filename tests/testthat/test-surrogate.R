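test_that("surrogate outputs are strictly positive for random weights", {
  spec <- network_spec(2, 4, n_observed = 1, n_unobserved = 2)
  set.seed(3)
  for (i in 1:40) {
    w <- init_network(spec)
    out <- forward_moments(w, spec, runif(25, 0, 24),
                           t_range = c(0, 24))
    expect_true(all(out > 0))
  }
})

test_that("min-max scaling and unscaling are an inverse pair", {
  sc <- scaling_spec(x_min = c(0.2, 0.01), x_max = c(27, 3))
  x <- c(5, 1.2)
  scaled <- (x - sc$x_min) / (sc$x_max - sc$x_min)
  expect_equal(sc$x_min + (sc$x_max - sc$x_min) * scaled, x)
  expect_error(scaling_spec(1, 1), "exceed")
})

test_that("identity scaling returns raw transformed network values", {
  spec <- network_spec(2, 3)
  set.seed(4)
  w <- init_network(spec)
  t <- seq(0, 1, length.out = 7)
  raw <- forward_moments(w, spec, t, identity_scaling(spec))
  # manual forward pass
  a <- matrix(t, 1)
  for (l in 1:2) a <- tanh(w[[l]]$W %*% a + w[[l]]$b)
  z <- w[[3]]$W %*% a + w[[3]]$b
  manual <- t(log1p(exp(z)))
  manual[, 2] <- manual[, 2] + spec$spread_bias
  expect_equal(unname(raw), unname(manual), tolerance = 1e-10)
})

test_that("automatic time derivatives match central finite differences", {
  spec <- network_spec(2, 5, n_observed = 1, n_unobserved = 1)
  sc <- scaling_spec(x_min = c(0, 0.1, 0), x_max = c(25, 4, 25))
  set.seed(5)
  for (rep in 1:5) {
    w <- init_network(spec)
    t <- runif(6, 0.5, 23)
    h <- 1e-4
    ad <- time_derivatives(w, spec, t, sc, t_range = c(0, 24))
    fd <- (forward_moments(w, spec, t + h, sc, t_range = c(0, 24)) -
             forward_moments(w, spec, t - h, sc, t_range = c(0, 24))) / (2 * h)
    expect_equal(ad, fd, tolerance = 1e-6)
  }
})

test_that("log-warped time input keeps derivatives exact", {
  spec <- network_spec(2, 6, n_observed = 1, n_unobserved = 0)
  sc <- scaling_spec(x_min = c(0.2, 0.01), x_max = c(27, 3))
  set.seed(6)
  w <- init_network(spec)
  t <- c(0.75, 1.5, 24, 500, 2000)
  h <- 1e-4
  ad <- time_derivatives(w, spec, t, sc, t_range = c(0, 2376),
                         input_log_time = TRUE)
  fd <- (forward_moments(w, spec, t + h, sc, c(0, 2376),
                         input_log_time = TRUE) -
           forward_moments(w, spec, t - h, sc, c(0, 2376),
                           input_log_time = TRUE)) / (2 * h)
  expect_equal(ad, fd, tolerance = 1e-6)
})

test_that("derivative unscaling is linear in the output span", {
  spec <- network_spec(1, 3)
  set.seed(7)
  w <- init_network(spec)
  t <- seq(0.1, 0.9, length.out = 5)
  d1 <- time_derivatives(w, spec, t, scaling_spec(c(0, 0), c(1, 1)))
  d2 <- time_derivatives(w, spec, t, scaling_spec(c(0, 0), c(2, 2)))
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
  # the printed-formula variant squares the factor on the SD channel only
  spec_sd <- network_spec(1, 3, spread = "sd")
  d3 <- time_derivatives(w, spec_sd, t, scaling_spec(c(0, 0), c(2, 3)),
                         paper_literal_sd_scaling = TRUE)
  d4 <- time_derivatives(w, spec_sd, t, scaling_spec(c(0, 0), c(2, 3)))
  expect_equal(d3[, 1], d4[, 1])
  expect_equal(d3[, 2], 3 * d4[, 2], tolerance = 1e-12)
})

test_that("weight initialisation is reproducible under a seed", {
  spec <- network_spec(2, 30, n_observed = 1, n_unobserved = 3,
                       spread = "sd")
  set.seed(99); w1 <- init_network(spec)
  set.seed(99); w2 <- init_network(spec)
  expect_identical(w1, w2)
  t <- seq(1, 2000, length.out = 11)
  expect_identical(forward_moments(w1, spec, t, t_range = c(0, 2376)),
                   forward_moments(w2, spec, t, t_range = c(0, 2376)))
})

test_that("weight flattening round-trips", {
  spec <- network_spec(2, 3, n_observed = 1, n_unobserved = 1)
  set.seed(8)
  w <- init_network(spec)
  flat <- dpinns:::flatten_weights(w)
  expect_length(flat, dpinns:::n_weight_params(spec))
  expect_equal(dpinns:::unflatten_weights(flat, spec), w)
})
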