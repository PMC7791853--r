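# Synthetic cohorts of Meier-score recovery trajectories. The generator
# mirrors the hierarchical structure assumed by the decay model: per-horse
# parameters drawn around the population values with diagonal between-horse
# variances, additive Gaussian residual, scores clipped to the attainable
# 0-12 range and rounded to integers (clinical scores are integers).

#' Draw per-horse individual parameters
#'
#' Each horse's \eqn{(\log\theta_{0i}, \log\theta_{1i}, \theta_{2i})} is drawn
#' independently normal around the population fixed effects with the
#' corresponding between-horse variances. \eqn{\theta_{2i}} lives on the
#' natural scale and can in principle be drawn non-positive when
#' \code{omega2} is large; such draws are resampled and counted in the
#' \code{"n_resampled_theta2"} attribute.
#'
#' @param pop a [population_params()].
#' @param n number of horses (>= 1).
#' @param seed RNG seed (reproducible draws for a fixed seed).
#' @return An [individual_effects()] data frame with \code{n} rows.
#' @export
sample_individual_params <- function(pop, n, seed = NULL) {
  pop <- as_population_params(pop)
  if (!is_count(n)) stop("`n` must be a positive integer", call. = FALSE)
  with_seed(seed, {
    l0 <- rnorm(n, pop$log_theta0, sqrt(pop$omega0))
    l1 <- rnorm(n, pop$log_theta1, sqrt(pop$omega1))
    t2 <- rnorm(n, pop$theta2, sqrt(pop$omega2))
    n_resampled <- 0L
    while (any(bad <- t2 <= 0)) {
      n_resampled <- n_resampled + sum(bad)
      t2[bad] <- rnorm(sum(bad), pop$theta2, sqrt(pop$omega2))
      if (n_resampled > 10000L * n) stop("theta2 resampling did not terminate",
                                         call. = FALSE)
    }
    eff <- individual_effects(sprintf("horse_%03d", seq_len(n)), l0, l1, t2)
    attr(eff, "n_resampled_theta2") <- n_resampled
    eff
  })
}

#' Simulate one score trajectory
#'
#' Evaluates the structural decay curve at the visit days for one horse and
#' adds independent N(0, sigma^2) residuals. The day-0 structural value is
#' exactly \eqn{\theta_{0i}} (the convention \eqn{0^{\theta_2} = 0} is used
#' for \eqn{\theta_2 > 0}). Optionally clips to the attainable 0-12 score
#' range and rounds to the nearest integer.
#'
#' @param effects a one-row [individual_effects()] (or a row of one).
#' @param days non-negative, strictly increasing visit days.
#' @param sigma residual SD (>= 0).
#' @param seed RNG seed.
#' @param clip clip scores into [0, 12]?
#' @param round_to_integer round scores to integers (after clipping)?
#' @param group_label trajectory label: \code{"fast"}, \code{"slow"} or
#'   \code{"unknown"}.
#' @return A long-format data frame: \code{horse_id}, \code{day},
#'   \code{score}, \code{group_label}.
#' @export
simulate_trajectory <- function(effects, days = c(0, 4, 9, 14, 25, 42),
                                sigma = 0, seed = NULL, clip = TRUE,
                                round_to_integer = TRUE,
                                group_label = "unknown") {
  stopifnot(nrow(effects) == 1L)
  .check_days(days)
  if (!(is.numeric(sigma) && length(sigma) == 1L && sigma >= 0)) {
    stop("`sigma` must be a single number >= 0", call. = FALSE)
  }
  mu <- structural_mean(effects, days)
  score <- with_seed(seed, mu + rnorm(length(days), 0, sigma))
  score <- .finish_scores(score, clip, round_to_integer)
  data.frame(horse_id = effects$horse_id, day = as.integer(days),
             score = score, group_label = group_label,
             stringsAsFactors = FALSE)
}

.check_days <- function(days) {
  if (!(is.numeric(days) && length(days) >= 1L && all(is.finite(days)) &&
        all(days >= 0) && !is.unsorted(days, strictly = TRUE))) {
    stop("`days` must be non-negative and strictly increasing", call. = FALSE)
  }
}

.finish_scores <- function(score, clip, round_to_integer) {
  if (clip) score <- pmin(pmax(score, 0), 12)
  if (round_to_integer) score <- round(score)
  score
}

#' Simulate a slow-improvement (waxing/waning) trajectory
#'
#' A minority of clinical cases do not follow the smooth decay: their scores
#' stay high at day 14 (range 4-10 in the study cohort) and rise and fall
#' over the 42 days. The generative mechanism here is a stated invention
#' constrained only by those observables: the decay rate is slowed so the
#' day-14 structural score falls in the target band, and one Gaussian-shaped
#' relapse bump is added later in the period; the day-14 score is then
#' enforced into [4, 10] and non-monotonicity is guaranteed.
#'
#' With \code{relapse_amplitude = 0} and \code{slow_decay = FALSE} the
#' trajectory degenerates to an ordinary decay trajectory (no day-14 or
#' non-monotonicity enforcement is applied then).
#'
#' @param baseline a one-row [individual_effects()] giving the horse's
#'   baseline severity and decay parameters.
#' @param days visit days.
#' @param seed RNG seed.
#' @param sigma residual SD in score units.
#' @param relapse_amplitude either \code{NULL} (draw uniformly from
#'   \code{relapse_range}) or a fixed amplitude; 0 disables the bump.
#' @param relapse_range range the amplitude is drawn from, score units.
#' @param slow_decay slow the decay so day 14 is still in the 4-10 band?
#' @param clip,round_to_integer as in [simulate_trajectory()].
#' @return A long-format trajectory data frame labelled \code{"slow"} (or the
#'   baseline label when fully degenerate).
#' @export
simulate_slow_improver <- function(baseline, days = c(0, 4, 9, 14, 25, 42),
                                   seed = NULL, sigma = 0.99,
                                   relapse_amplitude = NULL,
                                   relapse_range = c(1.5, 3.5),
                                   slow_decay = TRUE,
                                   clip = TRUE, round_to_integer = TRUE) {
  stopifnot(nrow(baseline) == 1L)
  .check_days(days)
  degenerate <- isTRUE(!slow_decay) && !is.null(relapse_amplitude) &&
    relapse_amplitude == 0
  if (degenerate) {
    return(simulate_trajectory(baseline, days, sigma, seed, clip,
                               round_to_integer, group_label = "fast"))
  }
  with_seed(seed, {
    for (attempt in 1:25) {
      eff <- baseline
      if (slow_decay) {
        # pick the decay rate so the structural day-14 score sits in-band
        target14 <- runif(1, 4.5, 8)
        target14 <- min(target14, 0.95 * exp(baseline$log_theta0_i))
        rate <- (baseline$log_theta0_i - log(target14)) / 14^baseline$theta2_i
        rate <- max(rate, 1e-4)
        eff$log_theta1_i <- log(rate)
      }
      amp <- if (is.null(relapse_amplitude)) {
        runif(1, relapse_range[1], relapse_range[2])
      } else relapse_amplitude
      centre <- runif(1, 18, 38)
      width <- runif(1, 5, 10)
      mu <- structural_mean(eff, days) + amp * exp(-((days - centre) / width)^2)
      score <- .finish_scores(mu + rnorm(length(days), 0, sigma),
                              clip, round_to_integer)
      i14 <- match(14, days)
      ok14 <- is.na(i14) || (score[i14] >= 4 && score[i14] <= 10)
      nonmono <- any(diff(score) > 0)
      if (ok14 && nonmono) break
    }
    if (!is.na(i14) && (score[i14] < 4 || score[i14] > 10)) {
      score[i14] <- pmin(pmax(score[i14], 4), 10)  # enforce the band
    }
    if (!any(diff(score) > 0)) {
      # force one relapse: raise a late visit above its predecessor
      j <- max(2L, which.max(days > 14))
      score[j] <- min(12, score[j - 1] + max(1, round(amp)))
    }
    data.frame(horse_id = eff$horse_id, day = as.integer(days),
               score = score, group_label = "slow", stringsAsFactors = FALSE)
  })
}

#' Simulate a cohort of recovery trajectories
#'
#' Draws \code{n} horses' individual parameters around \code{pop}, simulates
#' each trajectory at the study visit days (0, 4, 9, 14, 25 and 42 by
#' default), and stacks them in long format. A fraction of horses can be
#' generated as slow improvers (waxing/waning trajectories); the default
#' cohort is the 64-horse fast-improvement group.
#'
#' @param pop a [population_params()] (defaults: published fast-group fit).
#' @param n number of horses (default 64, the fast group size).
#' @param days visit days.
#' @param seed RNG seed; fixed seed gives a bit-identical cohort.
#' @param clip,round_to_integer see [simulate_trajectory()].
#' @param slow_fraction fraction of horses simulated as slow improvers
#'   (default 0; the full study cohort used 16/80 = 0.2).
#' @param signs also decompose each visit's total into the five per-criterion
#'   scores via [allocate_signs()] (requires integer scores)?
#' @return A \code{"laminitis_cohort"} data frame in long format:
#'   \code{horse_id}, \code{day}, \code{score}, \code{group_label} and,
#'   with \code{signs = TRUE}, the five per-sign point columns. The
#'   generating [individual_effects()] are attached as attribute
#'   \code{"effects"}.
#' @examples
#' coh <- simulate_cohort(seed = 1)
#' median_trajectory(coh)
#' @export
simulate_cohort <- function(pop = population_params(), n = 64,
                            days = c(0, 4, 9, 14, 25, 42), seed = NULL,
                            clip = TRUE, round_to_integer = TRUE,
                            slow_fraction = 0, signs = FALSE) {
  pop <- as_population_params(pop)
  if (!is_count(n)) stop("`n` must be a positive integer", call. = FALSE)
  .check_days(days)
  if (!(is.numeric(slow_fraction) && slow_fraction >= 0 && slow_fraction <= 1)) {
    stop("`slow_fraction` must be in [0, 1]", call. = FALSE)
  }
  seeds <- derive_seeds(seed, n + 2L)
  eff <- sample_individual_params(pop, n, seed = seeds[1])
  n_slow <- round(slow_fraction * n)
  slow_idx <- if (n_slow > 0) {
    with_seed(seeds[2], sort(sample.int(n, n_slow)))
  } else integer(0)
  rows <- lapply(seq_len(n), function(i) {
    if (i %in% slow_idx) {
      simulate_slow_improver(eff[i, ], days, seed = seeds[i + 2L],
                             sigma = pop$sigma, clip = clip,
                             round_to_integer = round_to_integer)
    } else {
      simulate_trajectory(eff[i, ], days, sigma = pop$sigma,
                          seed = seeds[i + 2L], clip = clip,
                          round_to_integer = round_to_integer,
                          group_label = "fast")
    }
  })
  cohort <- do.call(rbind, rows)
  class(cohort) <- c("laminitis_cohort", "data.frame")
  attr(cohort, "effects") <- eff
  if (signs) {
    if (!round_to_integer) {
      stop("`signs = TRUE` requires integer scores (`round_to_integer = TRUE`)",
           call. = FALSE)
    }
    cohort <- allocate_signs(cohort, seed = seeds[n + 2L] %% .Machine$integer.max)
  }
  cohort
}

#' Simulate the full 80-horse study cohort
#'
#' Convenience wrapper: 64 fast improvers plus 16 slow improvers
#' (\code{slow_fraction = 0.2}), matching the composition of the clinical
#' cohort.
#'
#' @param pop,seed,days,... passed to [simulate_cohort()].
#' @return A \code{"laminitis_cohort"} data frame of 80 horses.
#' @export
simulate_study_cohort <- function(pop = population_params(), seed = NULL,
                                  days = c(0, 4, 9, 14, 25, 42), ...) {
  simulate_cohort(pop, n = 80, days = days, seed = seed,
                  slow_fraction = 0.2, ...)
}

# Base per-total decomposition into the five criterion scores. The fill
# order encodes the observed resolution order (totals shrink as horses
# improve): weight shifting and foot lift points are the first to go, then
# pulse, then walk, with circle points persisting longest. A total of 12 is
# only attainable through the severe-walk branch (2+2+6+skip+2).
.sign_increments <- list(
  c("circle_pts", 1), c("walk_pts", 1), c("pulse_pts", 2), c("circle_pts", 1),
  c("walk_pts", 1), c("weight_shifting_pts", 2), c("foot_lift_pts", 1),
  c("foot_lift_pts", 1), c("circle_pts", 1)
)

.decompose_total <- function(total) {
  out <- c(weight_shifting_pts = 0L, foot_lift_pts = 0L, walk_pts = 0L,
           circle_pts = 0L, pulse_pts = 0L)
  if (total == 12L) {
    return(c(weight_shifting_pts = 2L, foot_lift_pts = 2L, walk_pts = 6L,
             circle_pts = 0L, pulse_pts = 2L))
  }
  remaining <- total
  for (inc in .sign_increments) {
    sz <- as.integer(inc[[2]])
    if (remaining >= sz) {
      out[inc[[1]]] <- out[inc[[1]]] + sz
      remaining <- remaining - sz
    }
    if (remaining == 0L) break
  }
  out
}

#' Decompose visit totals into per-sign scores
#'
#' Splits each visit's integer total into the five Meier criterion scores,
#' respecting the per-criterion caps (weight shifting 2, foot lift 2, walk
#' 0/1/2/6, circle 3, pulse 2) and the qualitative resolution order seen
#' clinically: weight shifting and foot lift resolve earliest, then the
#' digital pulse, then gait at the walk, with gait at the circle persisting
#' longest. A total of 12 has the unique severe-walk decomposition
#' (2, 2, 6, skipped, 2). With a seed, one point is occasionally moved from
#' walk to circle (when caps allow) to emulate the near-parallel recovery of
#' the two locomotor signs; the row sums are always preserved.
#'
#' @param cohort a long-format cohort data frame with integer \code{score}.
#' @param seed RNG seed for the walk-to-circle jitter.
#' @param jitter_prob probability of the walk-to-circle point move per visit.
#' @return The cohort with the five per-sign point columns and a
#'   \code{circle_skipped} flag appended.
#' @export
allocate_signs <- function(cohort, seed = NULL, jitter_prob = 0.3) {
  cohort <- as_cohort(cohort)
  sc <- cohort$score
  if (!all(is.finite(sc) & sc == floor(sc) & sc >= 0 & sc <= 12)) {
    stop("per-sign allocation requires integer totals in the attainable ",
         "range 0..12", call. = FALSE)
  }
  base <- t(vapply(as.integer(sc), .decompose_total, integer(5)))
  with_seed(seed, {
    move <- runif(nrow(base)) < jitter_prob &
      base[, "walk_pts"] >= 1L & base[, "walk_pts"] != 6L &
      base[, "circle_pts"] >= 1L & base[, "circle_pts"] <= 2L
    base[move, "walk_pts"] <- base[move, "walk_pts"] - 1L
    base[move, "circle_pts"] <- base[move, "circle_pts"] + 1L
  })
  out <- cbind(cohort, as.data.frame(base),
               data.frame(circle_skipped = base[, "walk_pts"] == 6L))
  class(out) <- c("laminitis_cohort", "data.frame")
  attr(out, "effects") <- attr(cohort, "effects")
  out
}
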