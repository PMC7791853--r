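test_that("Meier scoring reproduces hand-evaluated exams", {
  # identity case: a sound horse scores 0 on every criterion
  s0 <- score_meier(meier_exam())
  expect_equal(s0$total, 0L)
  expect_equal(unlist(s0[1:5], use.names = FALSE), rep(0L, 5))
  expect_false(s0$circle_skipped)

  # worst case: severe walk skips the circle, total still reaches 12
  s12 <- score_meier(meier_exam(
    weight_shifting = "present", foot_lift_left = "unable",
    foot_lift_right = "unable", gait_walk = "severe",
    gait_circle = "not_assessed", pulse_left = "bounding",
    pulse_right = "bounding"))
  expect_equal(s12$total, 12L)
  expect_true(s12$circle_skipped)
  expect_equal(s12$circle_pts, 0L)
  expect_equal(s12$walk_pts, 6L)

  # mixed exam, hand sum 2 + 1 + 2 + 2 + 2 = 9 (worst forelimb counts)
  s9 <- score_meier(meier_exam(
    weight_shifting = "present", foot_lift_left = "reluctant",
    foot_lift_right = "prompt", gait_walk = "moderate",
    gait_circle = "moderate", pulse_left = "bounding",
    pulse_right = "normal"))
  expect_equal(s9$total, 9L)
  expect_equal(s9$foot_lift_pts, 1L)
  expect_equal(s9$pulse_pts, 2L)
})

test_that("the severe-walk skip rule is enforced in both directions", {
  expect_error(meier_exam(gait_walk = "severe", gait_circle = "mild"),
               "skips the circle")
  expect_error(meier_exam(gait_walk = "mild", gait_circle = "not_assessed"),
               "not_assessed")
  expect_error(meier_exam(gait_walk = "terrible"), "gait_walk")
})

test_that("exhaustive enumeration: totals span exactly 0..12", {
  totals <- enumerate_attainable_totals()
  expect_equal(totals, 0:12)
  expect_equal(min(totals), 0L)
  expect_equal(max(totals), 12L)
})

test_that("worsening any single criterion never decreases the total", {
  grid <- enumerate_meier_exams()
  fields <- setdiff(names(grid), character(0))
  # sample the enumeration for speed; structure is exhaustive per field
  idx <- seq(1, nrow(grid), by = 7)
  for (i in idx) {
    exam <- as.list(grid[i, ])
    base <- score_meier(do.call(meier_exam, exam))$total
    for (f in fields) {
      worse <- worsen_exam(exam, f)
      if (is.null(worse)) next
      expect_gte(score_meier(worse)$total, base)
    }
  }
})

test_that("Obel grading is total and matches the grade descriptions", {
  expect_equal(grade_obel(obel_exam()), 0L)
  expect_equal(grade_obel(obel_exam(
    sound_at_walk = FALSE, stilted_at_walk = TRUE,
    turns_with_great_difficulty = TRUE)), 2L)
  expect_equal(grade_obel(obel_exam(
    sound_at_walk = FALSE, reluctant_to_walk = TRUE,
    moves_only_if_forced = TRUE)), 4L)
  expect_equal(grade_obel(obel_exam(
    weight_shift_at_rest = TRUE, stilted_at_trot_and_turn = TRUE)), 1L)
  expect_equal(grade_obel(obel_exam(
    sound_at_walk = FALSE, reluctant_to_walk = TRUE,
    forelimb_liftable = "with_great_difficulty")), 3L)

  # totality over every valid flag combination
  flags <- expand.grid(ws = c(TRUE, FALSE), sw = c(TRUE, FALSE),
                       st = c(TRUE, FALSE), sk = c(TRUE, FALSE),
                       td = c(TRUE, FALSE),
                       fl = c("willingly", "with_great_difficulty",
                              "not_liftable"),
                       rw = c(TRUE, FALSE), mf = c(TRUE, FALSE),
                       stringsAsFactors = FALSE)
  valid <- !(flags$mf & !flags$rw) & !(flags$sw & flags$sk)
  flags <- flags[valid, ]
  grades <- vapply(seq_len(nrow(flags)), function(i) {
    grade_obel(obel_exam(flags$ws[i], flags$sw[i], flags$st[i], flags$sk[i],
                         flags$td[i], flags$fl[i], flags$rw[i], flags$mf[i]))
  }, integer(1))
  expect_true(all(grades %in% 0:4))
})

test_that("Obel exam invariants are enforced", {
  expect_error(obel_exam(moves_only_if_forced = TRUE), "reluctant_to_walk")
  expect_error(obel_exam(sound_at_walk = TRUE, stilted_at_walk = TRUE),
               "mutually exclusive")
})

test_that("inclusion predicate equals (meier >= 5) and (obel >= 1) exhaustively", {
  expect_true(check_inclusion(5, 1))
  expect_false(check_inclusion(4, 4))
  expect_false(check_inclusion(12, 0))
  for (m in 0:12) for (g in 0:4) {
    expect_identical(check_inclusion(m, g), m >= 5 && g >= 1)
  }
  expect_error(check_inclusion(13, 1), "0..12")
  expect_error(check_inclusion(5, 5), "0..4")
  expect_error(check_inclusion(-1, 1), "0..12")
})

test_that("every valid exam's total is attainable", {
  attainable <- enumerate_attainable_totals()
  grid <- enumerate_meier_exams()
  idx <- seq(1, nrow(grid), by = 11)
  for (i in idx) {
    tot <- score_meier(do.call(meier_exam, as.list(grid[i, ])))$total
    expect_true(tot %in% attainable)
  }
})
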