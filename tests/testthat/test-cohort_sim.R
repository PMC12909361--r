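test_that("population sampling matches the specified moments", {
  spec <- population_spec(means = c(Vd = 15, ke = 0.115),
                          cvs = c(Vd = 0.1, ke = 0.4),
                          sigma = 0.1, n_subjects = 30)
  set.seed(1)
  draws <- sample_parameters(spec, n = 2e5)
  expect_equal(mean(draws[, "Vd"]), 15, tolerance = 0.01)
  expect_equal(sd(draws[, "Vd"]) / mean(draws[, "Vd"]), 0.1,
               tolerance = 0.01)
  expect_equal(sd(draws[, "ke"]) / mean(draws[, "ke"]), 0.4,
               tolerance = 0.01)
  expect_lt(abs(cor(log(draws[, 1]), log(draws[, 2]))), 0.01)
  # near-degenerate CVs collapse to the mean
  tight <- population_spec(means = c(Vd = 15), cvs = c(Vd = 1e-8),
                           corr = diag(1))
  expect_equal(as.numeric(sample_parameters(tight, 10)), rep(15, 10),
               tolerance = 1e-6)
  expect_error(population_spec(c(a = 1, b = 2), c(a = 0.1, b = 0.1),
                               matrix(c(1, 2, 2, 1), 2, 2)),
               "positive semidefinite")
})

test_that("observation simulation applies the multiplicative error model", {
  draws <- cbind(Vd = c(15, 12), ke = c(log(2) / 6, 0.1))
  sched <- c(0.5, 1, 2, 6, 12, 24)
  noiseless <- simulate_observations(draws, sched, 300, sigma = 0)
  expect_equal(noiseless$observed[1, 4], 10, tolerance = 1e-12)
  expect_equal(noiseless$observed, noiseless$true)
  set.seed(2)
  big <- simulate_observations(matrix(rep(c(15, 0.115), each = 300),
                                      ncol = 2,
                                      dimnames = list(NULL, c("Vd", "ke"))),
                               sched, 300, sigma = 0.1)
  resid <- log(big$observed) - log(big$true)
  expect_equal(sd(resid), 0.1, tolerance = 0.01)
  expect_error(simulate_observations(draws, c(2, 1), 300, 0.1), "increasing")
})

test_that("aggregation computes unbiased summaries over unmasked subjects", {
  cohort <- structure(list(times = c(1, 2),
                           true = rbind(c(1, 4), c(3, 6), c(5, 8)),
                           observed = rbind(c(1, 4), c(3, 6), c(5, 8)),
                           mask = matrix(TRUE, 3, 2)),
                      class = "cohort_data")
  agg <- aggregate_cohort(cohort)
  expect_equal(agg$mean, c(3, 6))
  expect_equal(agg$var, c(4, 4))
  expect_equal(agg$n, c(3L, 3L))
  # mask one subject at the first time: hand-computed 2-subject summary
  cohort$mask[2, 1] <- FALSE
  agg2 <- aggregate_cohort(cohort)
  expect_equal(agg2$mean[1], 3)
  expect_equal(agg2$var[1], 8)
  expect_equal(agg2$n[1], 2L)
  # identical values give zero variance
  same <- cohort
  same$observed <- matrix(2, 3, 2)
  same$mask <- matrix(TRUE, 3, 2)
  expect_equal(aggregate_cohort(same)$var, c(0, 0))
  # fewer than two observations drops the time point
  thin <- cohort
  thin$mask <- rbind(c(TRUE, TRUE), c(FALSE, TRUE), c(FALSE, TRUE))
  expect_warning(agg3 <- aggregate_cohort(thin), "dropped")
  expect_equal(agg3$time, 2)
})

test_that("missingness masks are sized and reproducible", {
  set.seed(3)
  study <- simulate_onecomp_study()
  expect_true(all(mask_missing(study$cohort, 0)$mask))
  set.seed(4); m1 <- mask_missing(study$cohort, 0.5)
  set.seed(4); m2 <- mask_missing(study$cohort, 0.5)
  expect_identical(m1$mask, m2$mask)
  expect_equal(sum(!m1$mask), 90)
  expect_error(mask_missing(study$cohort, 1), "fraction")
})

test_that("the default bolus study encodes the stated population", {
  set.seed(5)
  study <- simulate_onecomp_study()
  expect_equal(unname(study$truth),
               unname(c(log(2) / 6, 0.4 * log(2) / 6, 15, 1.5, 0.1)))
  expect_equal(study$data$time, c(0.5, 1, 2, 6, 12, 24))
  expect_equal(nrow(study$cohort$observed), 30)
  expect_equal(study$data$n, rep(30L, 6))
})

test_that("frozen residual errors reproduce across correlation scenarios", {
  eps <- matrix(rnorm(30 * 6, 0, 0.1), 30, 6)
  set.seed(6)
  s1 <- simulate_onecomp_study(rho = 0, eps = eps)
  set.seed(6)
  s2 <- simulate_onecomp_study(rho = 0.5, eps = eps)
  expect_equal(s1$cohort$observed / s1$cohort$true,
               s2$cohort$observed / s2$cohort$true, tolerance = 1e-12)
})

test_that("aggregated-moment precision tightens with cohort size", {
  # standard error of the aggregated mean at a fixed time scales as 1/sqrt(n)
  se_of_mean <- function(n, reps = 40) {
    sd(replicate(reps, {
      s <- simulate_onecomp_study(n_subjects = n)
      s$data$mean[4]
    }))
  }
  set.seed(7)
  ratio <- se_of_mean(20) / se_of_mean(320)
  expect_gt(ratio, 2)   # ideal sqrt(16) = 4
  expect_lt(ratio, 8)
})

test_that("mAb cohort scales dose with body weight and peaks at end of infusion", {
  set.seed(8)
  sim <- simulate_mab_cohort(n_subjects = 8, clp_cv = 1e-6,
                             weight_range = c(60, 60 + 1e-9),
                             schedule = c(0.5, 1, 1.5, 2, 6, 24, 240))
  # degenerate clearance and weight: no between-subject variability
  expect_lt(max(apply(sim$cohort$true, 2, sd)), 1e-4)
  # plasma peaks at the end of the 1.5 h infusion
  prof <- sim$cohort$true[1, ]
  expect_equal(which.max(prof), 3)
  set.seed(9)
  wide <- simulate_mab_cohort(n_subjects = 30)
  expect_true(all(wide$cohort$weights >= 50 & wide$cohort$weights <= 75))
  expect_equal(nrow(wide$data), 15)
})
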