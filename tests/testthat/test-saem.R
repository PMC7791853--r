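test_that("SAEM recovers fixed effects in the near-deterministic limit", {
  pop <- population_params(omega0 = 0, omega1 = 0, omega2 = 0, sigma = 0.01)
  coh <- simulate_cohort(pop, n = 20, seed = 5, clip = FALSE,
                         round_to_integer = FALSE)
  fit <- suppressWarnings(saem_fit(coh, settings = saem_settings(seed = 1)))
  expect_lt(abs(fit$estimates$log_theta0 - 2.07), 0.05)
  expect_lt(abs(fit$estimates$log_theta1 + 1.95), 0.05)
  expect_lt(abs(fit$estimates$theta2 - 1.16), 0.05)
})

test_that("degenerate cohorts are rejected with a diagnostic", {
  one <- data.frame(horse_id = "a", day = c(0, 4, 9, 14), score = c(8, 5, 3, 1))
  expect_error(saem_fit(one), "at least 2 horses")
  short <- data.frame(horse_id = c("a", "b"), day = c(0, 0), score = c(8, 7))
  expect_error(saem_fit(short), ">= 2 visits")
  flat <- data.frame(horse_id = rep(c("a", "b"), each = 3),
                     day = rep(c(0, 4, 9), 2), score = rep(5, 6))
  expect_error(saem_fit(flat), "constant")
})

test_that("reported CV%, AIC and SE bookkeeping are internally consistent", {
  rf <- reference_fit()
  fit <- rf$fit
  # CV% is 100 * SE / |estimate| for every reported parameter
  expect_equal(fit$cv_percent,
               100 * fit$standard_errors / abs(fit$estimate_vector))
  # AIC identity holds exactly
  expect_equal(fit$aic, -2 * fit$loglik_estimate + 2 * fit$k)
  expect_equal(fit$k, 7L)
  expect_true(all(is.finite(fit$standard_errors)))
  expect_equal(nrow(fit$convergence_trace),
               fit$settings$n_burnin_iterations +
                 fit$settings$n_smoothing_iterations)
  expect_gte(fit$frac_theta2_nonpositive, 0)
  expect_lt(fit$frac_theta2_nonpositive, 0.5)
})

test_that("the published CV% arithmetic is reproduced on the printed pairs", {
  pairs <- list(c(se = 0.025, est = 2.07, cv = 1.2),
                c(se = 0.158, est = 1.95, cv = 8.1),
                c(se = 0.081, est = 1.16, cv = 7.0),
                c(se = 0.045, est = 0.99, cv = 4.6))
  for (p in pairs) {
    expect_lt(abs(100 * p[["se"]] / p[["est"]] - p[["cv"]]), 0.06)
  }
})

test_that("SAEM fit on reference conditions recovers the generating parameters", {
  rf <- reference_fit()
  est <- rf$fit$estimate_vector
  truth <- c(2.07, -1.95, 1.16)
  # within 3 reported standard errors of the published fit
  se <- c(0.025, 0.158, 0.081)
  for (j in 1:3) expect_lt(abs(est[j] - truth[j]), 3 * se[j])
  expect_lt(abs(est[["sigma"]] - 0.99), 3 * 0.045)
})

test_that("SAEM agrees with the two-stage oracle at low residual noise", {
  # conditions where per-horse least squares is well identified: moderate
  # between-horse rate variance, low residual noise (the two-stage route is
  # biased when horses' scores hit the zero floor early)
  pop <- population_params(omega1 = 0.1, omega2 = 0.02, sigma = 0.1)
  coh <- simulate_cohort(pop, n = 40, seed = 17, clip = FALSE,
                         round_to_integer = FALSE)
  fit <- suppressWarnings(saem_fit(coh, settings = saem_settings(seed = 3)))
  orc <- suppressWarnings(oracle_fit_two_stage(coh))
  expect_lt(abs(fit$estimates$log_theta0 - orc$log_theta0), 0.2)
  expect_lt(abs(fit$estimates$log_theta1 - orc$log_theta1), 0.2)
  expect_lt(abs(fit$estimates$theta2 - orc$theta2), 0.2)
})

test_that("theta2 can be fixed at 1, shrinking the parameter count", {
  pop <- population_params(theta2 = 1, omega2 = 0)
  coh <- simulate_cohort(pop, n = 25, seed = 19, clip = FALSE,
                         round_to_integer = FALSE)
  fit <- suppressWarnings(
    saem_fit(coh, fix_theta2 = TRUE,
             settings = saem_settings(n_burnin_iterations = 150,
                                      n_smoothing_iterations = 60,
                                      seed = 2)))
  expect_equal(fit$k, 5L)
  expect_equal(fit$estimates$theta2, 1)
  expect_equal(fit$estimates$omega2, 0)
  expect_lt(abs(fit$estimates$log_theta0 - 2.07), 0.15)
})
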