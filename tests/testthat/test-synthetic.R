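test_that("individual parameters collapse to the population values when variances are 0", {
  pop <- population_params(omega0 = 0, omega1 = 0, omega2 = 0)
  eff <- sample_individual_params(pop, 3, seed = 1)
  expect_equal(eff$log_theta0_i, rep(2.07, 3))
  expect_equal(eff$log_theta1_i, rep(-1.95, 3))
  expect_equal(eff$theta2_i, rep(1.16, 3))
  expect_error(sample_individual_params(pop, 0), "positive integer")
  expect_error(population_params(omega1 = -0.1), "must be >= 0")
})

test_that("large-sample mean of log theta0 matches the generator", {
  eff <- sample_individual_params(reference_params(), 1e4, seed = 2024)
  expect_lt(abs(mean(eff$log_theta0_i) - 2.07), 3 * sqrt(0.025 / 1e4))
  # theta2 stays positive by construction
  expect_true(all(eff$theta2_i > 0))
})

test_that("noise-free trajectories equal the structural curve; sigma=0, theta2=1 is plain exponential", {
  eff <- individual_effects("h1", log(8), log(0.2), 1)
  tr <- simulate_trajectory(eff, days = c(0, 4, 9, 14), sigma = 0,
                            clip = FALSE, round_to_integer = FALSE)
  expect_equal(tr$score, 8 * exp(-0.2 * c(0, 4, 9, 14)))
  # population-structural check with all variances and sigma zero
  pop <- population_params(omega0 = 0, omega1 = 0, omega2 = 0, sigma = 1)
  eff2 <- sample_individual_params(pop, 2, seed = 1)
  tr2 <- simulate_trajectory(eff2[1, ], sigma = 0, clip = FALSE,
                             round_to_integer = FALSE)
  expect_equal(tr2$score, structural_mean(eff2[1, ], tr2$day))
})

test_that("cohort simulation is reproducible, in range, and correctly shaped", {
  c1 <- simulate_cohort(seed = 5)
  c2 <- simulate_cohort(seed = 5)
  expect_identical(c1, c2)
  expect_equal(length(unique(c1$horse_id)), 64L)
  expect_equal(nrow(c1), 64L * 6L)
  expect_true(all(c1$score >= 0 & c1$score <= 12))
  expect_true(all(c1$score == round(c1$score)))
  c3 <- simulate_cohort(seed = 6)
  expect_false(identical(c1$score, c3$score))
})

test_that("structural mean is strictly decreasing in time for positive rates", {
  eff <- sample_individual_params(reference_params(), 20, seed = 3)
  grid <- seq(0, 42, by = 0.5)
  for (i in seq_len(20)) {
    mu <- structural_mean(eff[i, ], grid)
    expect_true(all(diff(mu) < 0))
  }
})

test_that("slow improvers stay in the day-14 band and wax and wane", {
  pop <- reference_params()
  for (s in 1:12) {
    eff <- sample_individual_params(pop, 1, seed = s)
    tr <- simulate_slow_improver(eff, seed = 100 + s)
    expect_equal(tr$group_label[1], "slow")
    s14 <- tr$score[tr$day == 14]
    expect_gte(s14, 4)
    expect_lte(s14, 10)
    expect_true(any(diff(tr$score) > 0))
    expect_true(all(tr$score >= 0 & tr$score <= 12))
  }
})

test_that("slow improver degenerates to an ordinary decay trajectory", {
  eff <- sample_individual_params(reference_params(), 1, seed = 4)
  tr <- simulate_slow_improver(eff, seed = 9, relapse_amplitude = 0,
                               slow_decay = FALSE)
  ref <- simulate_trajectory(eff, sigma = 0.99, seed = 9,
                             group_label = "fast")
  expect_equal(tr, ref)
})

test_that("the study cohort mixes ~20% slow improvers", {
  coh <- simulate_study_cohort(seed = 8)
  expect_equal(length(unique(coh$horse_id)), 80L)
  tab <- table(coh$group_label[!duplicated(coh$horse_id)])
  expect_equal(unname(tab["slow"]), 16L)
  expect_equal(unname(tab["fast"]), 64L)
})

test_that("per-sign allocation respects caps, sums and the severe-walk rule", {
  signs <- c("weight_shifting_pts", "foot_lift_pts", "walk_pts",
             "circle_pts", "pulse_pts")
  coh <- simulate_cohort(seed = 21, signs = TRUE)
  expect_true(all(signs %in% names(coh)))
  expect_equal(rowSums(coh[, signs]), as.numeric(coh$score),
               ignore_attr = TRUE)
  expect_true(all(coh$weight_shifting_pts %in% c(0, 2)))
  expect_true(all(coh$foot_lift_pts %in% 0:2))
  expect_true(all(coh$walk_pts %in% c(0, 1, 2, 6)))
  expect_true(all(coh$circle_pts %in% 0:3))
  expect_true(all(coh$pulse_pts %in% c(0, 2)))
  expect_true(all(coh$circle_pts[coh$walk_pts == 6] == 0))

  # total 0 -> all signs 0
  z <- allocate_signs(data.frame(horse_id = "a", day = 0, score = 0))
  expect_equal(unlist(z[, signs], use.names = FALSE), rep(0L, 5))

  # total 12 -> the unique severe-walk decomposition, confirmed by the
  # enumeration oracle: every valid exam totalling 12 has these points
  grid <- enumerate_meier_exams()
  full <- lapply(seq_len(nrow(grid)), function(i) {
    score_meier(do.call(meier_exam, as.list(grid[i, ])))
  })
  twelves <- Filter(function(s) s$total == 12L, full)
  expect_gt(length(twelves), 0)
  for (s in twelves) {
    expect_equal(unlist(s[1:5], use.names = FALSE), c(2L, 2L, 6L, 0L, 2L))
  }
  a12 <- allocate_signs(data.frame(horse_id = "a", day = 0, score = 12))
  expect_equal(unlist(a12[, signs], use.names = FALSE), c(2L, 2L, 6L, 0L, 2L))
  expect_true(a12$circle_skipped)

  expect_error(allocate_signs(data.frame(horse_id = "a", day = 0, score = 13)),
               "0..12")
})

test_that("signs resolve in the clinically observed order", {
  coh <- simulate_cohort(seed = 31, signs = TRUE)
  rd <- sign_summary(coh)$resolution_day
  rd[is.na(rd)] <- Inf  # a sign that never resolves counts as latest
  expect_lte(rd[["weight_shifting_pts"]], rd[["pulse_pts"]])
  expect_lte(rd[["foot_lift_pts"]], rd[["pulse_pts"]])
  expect_lte(rd[["pulse_pts"]], rd[["walk_pts"]])
  expect_lte(rd[["walk_pts"]], rd[["circle_pts"]])
})
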