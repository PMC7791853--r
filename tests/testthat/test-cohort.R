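test_that("fast/slow partition applies the day-14 threshold", {
  coh <- data.frame(
    horse_id = rep(c("a", "b", "c"), each = 2),
    day = rep(c(0, 14), 3),
    score = c(8, 3,   # a: day-14 score 3 -> fast
              9, 4,   # b: day-14 score 4 -> slow
              7, 10)) # c: slow
  p <- partition_fast_slow(coh)
  expect_equal(p$fast_ids, "a")
  expect_equal(sort(p$slow_ids), c("b", "c"))
  expect_equal(length(p$unassigned_ids), 0L)
  # exhaustive and exclusive
  expect_equal(sort(c(p$fast_ids, p$slow_ids)), c("a", "b", "c"))
  expect_length(intersect(p$fast_ids, p$slow_ids), 0)
  # idempotent
  expect_equal(partition_fast_slow(coh), p)
})

test_that("horses missing the partition day are reported unassigned; empty cohorts work", {
  coh <- data.frame(horse_id = c("a", "a", "b"), day = c(0, 14, 0),
                    score = c(8, 2, 9))
  p <- partition_fast_slow(coh)
  expect_equal(p$unassigned_ids, "b")
  empty <- data.frame(horse_id = character(0), day = numeric(0),
                      score = numeric(0))
  pe <- partition_fast_slow(empty)
  expect_length(pe$fast_ids, 0)
  expect_length(pe$slow_ids, 0)
})

test_that("median trajectory matches hand computation and conventions", {
  coh <- hand_cohort()
  m <- median_trajectory(coh)
  expect_equal(m$day, c(0, 14))
  # even-n midpoint convention: median of 7,8,9,10 is 8.5; of 1,2,4,5 is 3
  expect_equal(m$median, c(8.5, 3))
  expect_equal(m$n, c(4L, 4L))
  # single-horse cohort: medians are that horse's scores
  one <- coh[coh$horse_id == "a", ]
  m1 <- median_trajectory(one)
  expect_equal(m1$median, one$score)
  # permutation invariance over horses
  perm <- coh[sample(nrow(coh)), ]
  expect_equal(median_trajectory(perm), m)
})

test_that("sign summary counts positives and medians per day", {
  sig <- c("weight_shifting_pts", "foot_lift_pts", "walk_pts",
           "circle_pts", "pulse_pts")
  coh <- data.frame(horse_id = c("a", "b", "c", "d"), day = 0,
                    score = c(2, 0, 0, 0))
  coh[sig] <- 0L
  coh$walk_pts <- c(2L, 0L, 0L, 0L)
  s <- sign_summary(coh)
  expect_equal(s$percent_positive$walk_pts, 25)
  expect_equal(s$medians$walk_pts, 0)
  expect_equal(unname(s$resolution_day["walk_pts"]), 0)
  # all-zero cohort
  z <- coh; z$walk_pts <- 0L; z$score <- 0
  sz <- sign_summary(z)
  expect_true(all(unlist(sz$medians[sig]) == 0))
  expect_true(all(unlist(sz$percent_positive[sig]) == 0))
  # missing columns get a clear diagnostic
  expect_error(sign_summary(hand_cohort()), "per-sign")
})

test_that("Mann-Whitney U: exact enumeration and invariants", {
  # complete separation: U = 0, exact two-sided P = 2 * 1/20
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method, "exact")
  # identical singletons: tie at midrank, U = n_a n_b / 2, P = 1
  r2 <- mann_whitney_u(5, 5)
  expect_equal(r2$U, 0.5)
  expect_equal(r2$p_value, 1)
  # U_a + U_b = n_a * n_b always
  set.seed(42)
  for (i in 1:20) {
    a <- sample(0:12, sample(2:8, 1), replace = TRUE)
    b <- sample(0:12, sample(2:8, 1), replace = TRUE)
    ua <- mann_whitney_u(a, b)$U
    ub <- mann_whitney_u(b, a)$U
    expect_equal(ua + ub, length(a) * length(b))
  }
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("exact P agrees with wilcox.test and the normal approximation", {
  set.seed(7)
  for (i in 1:15) {
    a <- round(rnorm(sample(4:8, 1), 5, 2), 1)
    b <- round(rnorm(sample(4:8, 1), 6, 2), 1)
    ex <- mann_whitney_u(a, b, method = "exact")
    ap <- mann_whitney_u(a, b, method = "normal")
    expect_lt(abs(ex$p_value - ap$p_value), 0.05)
    if (!any(duplicated(c(a, b)))) {
      # untied case: independent reference implementation agrees exactly
      w <- wilcox.test(a, b, exact = TRUE)
      expect_equal(ex$U, unname(w$statistic))
      expect_equal(ex$p_value, w$p.value)
    }
  }
})

test_that("partition recovers generator labels on mixed cohorts", {
  agree <- vapply(1:3, function(s) {
    coh <- simulate_study_cohort(seed = 400 + s)
    truth <- coh$group_label[!duplicated(coh$horse_id)]
    names(truth) <- coh$horse_id[!duplicated(coh$horse_id)]
    p <- partition_fast_slow(coh)
    called <- setNames(rep("fast", length(truth)), names(truth))
    called[p$slow_ids] <- "slow"
    mean(called == truth[names(called)])
  }, numeric(1))
  expect_gte(mean(agree), 0.9)
})
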