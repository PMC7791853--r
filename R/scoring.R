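# Executable clinical scoring rubrics: the Obel 0-4 lameness grade and the
# composite "modified Obel" (Meier) 0-12 laminitis severity score.

.meier_levels <- list(
  weight_shifting = c("absent", "present"),
  foot_lift       = c("prompt", "reluctant", "unable"),
  gait_walk       = c("normal", "mild", "moderate", "severe"),
  gait_circle     = c("normal", "mild", "moderate", "severe", "not_assessed"),
  pulse           = c("normal", "bounding")
)

.meier_points <- list(
  weight_shifting = c(absent = 0, present = 2),
  foot_lift       = c(prompt = 0, reluctant = 1, unable = 2),
  gait_walk       = c(normal = 0, mild = 1, moderate = 2, severe = 6),
  gait_circle     = c(normal = 0, mild = 1, moderate = 2, severe = 3,
                      not_assessed = 0),
  pulse           = c(normal = 0, bounding = 2)
)

.check_level <- function(value, field, allowed) {
  if (!(is.character(value) && length(value) == 1L && value %in% allowed)) {
    stop(sprintf("`%s` must be one of: %s", field,
                 paste(allowed, collapse = ", ")), call. = FALSE)
  }
  value
}

#' Construct a Meier-method clinical examination record
#'
#' One horse at one visit, observed through the three-stage Meier protocol:
#' the horse standing (weight shifting, forelimb lift), in motion on a hard
#' surface (gait at the walk, then turned in a circle), and digital pulse
#' palpation. A horse with severe difficulty walking is not forced to circle:
#' the circle assessment is skipped, so \code{gait_walk == "severe"} requires
#' (and is required by) \code{gait_circle == "not_assessed"}.
#'
#' @param weight_shifting \code{"absent"} or \code{"present"} (shifting weight
#'   between feet, abnormal lying, forelimbs placed in front of the body).
#' @param foot_lift_left,foot_lift_right response to gently lifting each
#'   forelimb: \code{"prompt"}, \code{"reluctant"} or \code{"unable"}.
#' @param gait_walk gait over ~30 m at the walk: \code{"normal"},
#'   \code{"mild"}, \code{"moderate"} or \code{"severe"}.
#' @param gait_circle gait turned on a short lead both directions:
#'   \code{"normal"}, \code{"mild"}, \code{"moderate"}, \code{"severe"}, or
#'   \code{"not_assessed"} (only when the walk was severe).
#' @param pulse_left,pulse_right digital pulse per forelimb: \code{"normal"}
#'   or \code{"bounding"}.
#' @return An object of class \code{"meier_exam"}.
#' @seealso [score_meier()]
#' @export
meier_exam <- function(weight_shifting = "absent",
                       foot_lift_left = "prompt", foot_lift_right = "prompt",
                       gait_walk = "normal", gait_circle = "normal",
                       pulse_left = "normal", pulse_right = "normal") {
  ex <- list(
    weight_shifting = .check_level(weight_shifting, "weight_shifting",
                                   .meier_levels$weight_shifting),
    foot_lift_left  = .check_level(foot_lift_left, "foot_lift_left",
                                   .meier_levels$foot_lift),
    foot_lift_right = .check_level(foot_lift_right, "foot_lift_right",
                                   .meier_levels$foot_lift),
    gait_walk       = .check_level(gait_walk, "gait_walk",
                                   .meier_levels$gait_walk),
    gait_circle     = .check_level(gait_circle, "gait_circle",
                                   .meier_levels$gait_circle),
    pulse_left      = .check_level(pulse_left, "pulse_left",
                                   .meier_levels$pulse),
    pulse_right     = .check_level(pulse_right, "pulse_right",
                                   .meier_levels$pulse)
  )
  if (ex$gait_walk == "severe" && ex$gait_circle != "not_assessed") {
    stop("severe gait at the walk skips the circle assessment: ",
         "`gait_circle` must be \"not_assessed\"", call. = FALSE)
  }
  if (ex$gait_walk != "severe" && ex$gait_circle == "not_assessed") {
    stop("`gait_circle` may only be \"not_assessed\" when `gait_walk` is ",
         "\"severe\"", call. = FALSE)
  }
  structure(ex, class = "meier_exam")
}

#' Score a Meier examination on the 0-12 scale
#'
#' Assigns points to the five clinical criteria and sums them: weight
#' shifting (0/2), forelimb lift (worst forelimb: 0/1/2), gait at the walk
#' (0/1/2/6), gait at the circle (0/1/2/3; 0 with \code{circle_skipped} set
#' when the walk was severe), and digital pulse (worst forelimb: 0/2).
#' Bilateral criteria take the maximum over forelimbs so the aggregate stays
#' on the stated 0-12 scale.
#'
#' @param exam a [meier_exam()].
#' @return An object of class \code{"meier_score"}: the five per-criterion
#'   point values, \code{total} (0-12) and the \code{circle_skipped} flag.
#' @examples
#' score_meier(meier_exam(weight_shifting = "present", gait_walk = "moderate",
#'                        gait_circle = "moderate", pulse_left = "bounding"))
#' @export
score_meier <- function(exam) {
  if (!inherits(exam, "meier_exam")) {
    exam <- do.call(meier_exam, as.list(exam))
  }
  pts <- .meier_points
  ws <- unname(pts$weight_shifting[exam$weight_shifting])
  fl <- max(pts$foot_lift[exam$foot_lift_left],
            pts$foot_lift[exam$foot_lift_right])
  wk <- unname(pts$gait_walk[exam$gait_walk])
  skipped <- exam$gait_circle == "not_assessed"
  ci <- unname(pts$gait_circle[exam$gait_circle])
  pu <- max(pts$pulse[exam$pulse_left], pts$pulse[exam$pulse_right])
  structure(list(
    weight_shifting_pts = as.integer(ws), foot_lift_pts = as.integer(fl),
    walk_pts = as.integer(wk), circle_pts = as.integer(ci),
    pulse_pts = as.integer(pu),
    total = as.integer(ws + fl + wk + ci + pu),
    circle_skipped = skipped
  ), class = "meier_score")
}

#' @export
print.meier_score <- function(x, ...) {
  cat(sprintf(
    "Meier score %d/12 (weight shifting %d, foot lift %d, walk %d, circle %d%s, pulse %d)\n",
    x$total, x$weight_shifting_pts, x$foot_lift_pts, x$walk_pts,
    x$circle_pts, if (x$circle_skipped) " [skipped]" else "", x$pulse_pts))
  invisible(x)
}

#' Construct an Obel-method examination record
#'
#' The observations needed to assign the classical Obel laminitis grade.
#'
#' @param weight_shift_at_rest horse shifts weight between forelimbs at rest.
#' @param sound_at_walk horse is sound at the walk.
#' @param stilted_at_trot_and_turn gait stilted at the trot in a straight
#'   line and on turning.
#' @param stilted_at_walk gait stilted at the walk.
#' @param turns_with_great_difficulty turning is markedly impaired.
#' @param forelimb_liftable \code{"willingly"}, \code{"with_great_difficulty"}
#'   or \code{"not_liftable"}.
#' @param reluctant_to_walk horse is reluctant to walk.
#' @param moves_only_if_forced horse will only move if forced to (implies
#'   \code{reluctant_to_walk}).
#' @return An object of class \code{"obel_exam"}.
#' @export
obel_exam <- function(weight_shift_at_rest = FALSE, sound_at_walk = TRUE,
                      stilted_at_trot_and_turn = FALSE,
                      stilted_at_walk = FALSE,
                      turns_with_great_difficulty = FALSE,
                      forelimb_liftable = "willingly",
                      reluctant_to_walk = FALSE,
                      moves_only_if_forced = FALSE) {
  flags <- list(weight_shift_at_rest = weight_shift_at_rest,
                sound_at_walk = sound_at_walk,
                stilted_at_trot_and_turn = stilted_at_trot_and_turn,
                stilted_at_walk = stilted_at_walk,
                turns_with_great_difficulty = turns_with_great_difficulty,
                reluctant_to_walk = reluctant_to_walk,
                moves_only_if_forced = moves_only_if_forced)
  for (nm in names(flags)) stop_if_not_flag(flags[[nm]], nm)
  .check_level(forelimb_liftable, "forelimb_liftable",
               c("willingly", "with_great_difficulty", "not_liftable"))
  if (moves_only_if_forced && !reluctant_to_walk) {
    stop("`moves_only_if_forced` implies `reluctant_to_walk`", call. = FALSE)
  }
  if (sound_at_walk && stilted_at_walk) {
    stop("`sound_at_walk` and `stilted_at_walk` are mutually exclusive",
         call. = FALSE)
  }
  structure(c(flags[1:5], list(forelimb_liftable = forelimb_liftable),
              flags[6:7]), class = "obel_exam")
}

#' Assign the Obel laminitis grade (0-4)
#'
#' Encodes the prose grade descriptions as a decision table with
#' highest-grade-wins precedence: 4 if the horse moves only when forced; 3 if
#' reluctant to walk and a forelimb lifts only with great difficulty; 2 if
#' stilted at the walk, turning with great difficulty, but a forelimb can be
#' lifted willingly; 1 if shifting weight at rest, sound at the walk, but
#' stilted at the trot and on turning; otherwise 0 (appears sound).
#'
#' @param exam an [obel_exam()].
#' @return An integer grade in 0-4.
#' @export
grade_obel <- function(exam) {
  if (!inherits(exam, "obel_exam")) exam <- do.call(obel_exam, as.list(exam))
  grade <-
    if (exam$moves_only_if_forced) 4L
    else if (exam$reluctant_to_walk &&
             exam$forelimb_liftable == "with_great_difficulty") 3L
    else if (exam$stilted_at_walk && exam$turns_with_great_difficulty &&
             exam$forelimb_liftable == "willingly") 2L
    else if (exam$weight_shift_at_rest && exam$sound_at_walk &&
             exam$stilted_at_trot_and_turn) 1L
    else 0L
  grade
}

#' Study inclusion predicate
#'
#' A case qualifies for the improvement study when laminitis is at least
#' Obel grade 1 of 4 and the Meier total is at least 5 of 12.
#'
#' @param meier_total integer Meier total, 0-12.
#' @param obel_grade integer Obel grade, 0-4.
#' @return \code{TRUE} iff \code{meier_total >= 5} and \code{obel_grade >= 1}.
#' @export
check_inclusion <- function(meier_total, obel_grade) {
  if (!is_count(meier_total, min = 0L) || meier_total > 12) {
    stop("`meier_total` must be an integer in 0..12", call. = FALSE)
  }
  if (!is_count(obel_grade, min = 0L) || obel_grade > 4) {
    stop("`obel_grade` must be an integer in 0..4", call. = FALSE)
  }
  meier_total >= 5 && obel_grade >= 1
}

#' Enumerate all valid Meier examinations
#'
#' Exhaustively generates every combination of criterion levels permitted by
#' the rubric, respecting the severe-walk/skip-circle rule. Used as a
#' brute-force oracle for properties of the 0-12 scale.
#'
#' @return A data frame with one row per valid exam (the seven level columns).
#' @keywords internal
#' @export
enumerate_meier_exams <- function() {
  grid <- expand.grid(
    weight_shifting = .meier_levels$weight_shifting,
    foot_lift_left = .meier_levels$foot_lift,
    foot_lift_right = .meier_levels$foot_lift,
    gait_walk = .meier_levels$gait_walk,
    gait_circle = .meier_levels$gait_circle,
    pulse_left = .meier_levels$pulse,
    pulse_right = .meier_levels$pulse,
    stringsAsFactors = FALSE
  )
  keep <- (grid$gait_walk == "severe") == (grid$gait_circle == "not_assessed")
  grid[keep, , drop = FALSE]
}

#' Attainable Meier totals by exhaustive enumeration
#'
#' Scores every valid examination and returns the sorted set of totals that
#' the rubric can actually produce.
#'
#' @return A sorted integer vector of attainable totals.
#' @examples
#' range(enumerate_attainable_totals())  # 0 and 12
#' @export
enumerate_attainable_totals <- function() {
  grid <- enumerate_meier_exams()
  totals <- vapply(seq_len(nrow(grid)), function(i) {
    score_meier(do.call(meier_exam, as.list(grid[i, ])))$total
  }, integer(1))
  sort(unique(totals))
}
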