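# Shared fixtures, built in code. One moderately sized reference fit is
# cached so several test files can interrogate it without refitting.

reference_params <- function() population_params()

# cohort simulated under the reference conditions but kept continuous and
# unclipped: the model the fitter assumes, free of the zero-floor artefact
continuous_cohort <- function(seed = 101, n = 64) {
  simulate_cohort(reference_params(), n = n, seed = seed,
                  clip = FALSE, round_to_integer = FALSE)
}

.cache <- new.env(parent = emptyenv())

reference_fit <- function() {
  if (is.null(.cache$fit)) {
    .cache$cohort <- continuous_cohort()
    .cache$fit <- suppressWarnings(
      saem_fit(.cache$cohort, settings = saem_settings(seed = 7)))
  }
  list(cohort = .cache$cohort, fit = .cache$fit)
}

# tiny hand-checkable cohort: 4 horses, 2 days
hand_cohort <- function() {
  data.frame(
    horse_id = rep(c("a", "b", "c", "d"), each = 2),
    day = rep(c(0, 14), 4),
    score = c(8, 2, 10, 4, 7, 1, 9, 5),
    stringsAsFactors = FALSE)
}

# worsen one criterion of a meier exam by one level, respecting the
# severe-walk skip rule; returns NULL when already at the worst level
worsen_exam <- function(exam, field) {
  orders <- list(
    weight_shifting = c("absent", "present"),
    foot_lift_left = c("prompt", "reluctant", "unable"),
    foot_lift_right = c("prompt", "reluctant", "unable"),
    gait_walk = c("normal", "mild", "moderate", "severe"),
    gait_circle = c("normal", "mild", "moderate", "severe"),
    pulse_left = c("normal", "bounding"),
    pulse_right = c("normal", "bounding"))
  lv <- orders[[field]]
  cur <- match(exam[[field]], lv)
  if (is.na(cur) || cur == length(lv)) return(NULL)
  exam[[field]] <- lv[cur + 1]
  if (field == "gait_walk" && exam[[field]] == "severe") {
    exam$gait_circle <- "not_assessed"
  }
  if (field == "gait_circle" && exam$gait_walk == "severe") return(NULL)
  do.call(meier_exam, exam)
}
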