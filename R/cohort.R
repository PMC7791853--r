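# Cohort-level descriptive machinery: fast/slow partition, median
# trajectories, per-sign summaries, Mann-Whitney U.

.sign_cols <- c("weight_shifting_pts", "foot_lift_pts", "walk_pts",
                "circle_pts", "pulse_pts")

# validate/coerce a long-format cohort data frame
as_cohort <- function(x, check_range = FALSE) {
  if (!is.data.frame(x)) stop("cohort must be a data frame", call. = FALSE)
  need <- c("horse_id", "day", "score")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("cohort is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(x$day) || !is.numeric(x$score)) {
    stop("`day` and `score` must be numeric", call. = FALSE)
  }
  dup <- duplicated(x[, c("horse_id", "day")])
  if (any(dup)) {
    d1 <- which(dup)[1]
    stop(sprintf("duplicate visit: horse %s at day %s",
                 x$horse_id[d1], x$day[d1]), call. = FALSE)
  }
  if (check_range && any(x$score < 0 | x$score > 12)) {
    bad <- which(x$score < 0 | x$score > 12)[1]
    stop(sprintf(
      "score %s for horse %s at day %s is outside the 0-12 Meier scale",
      format(x$score[bad]), x$horse_id[bad], x$day[bad]), call. = FALSE)
  }
  if (!inherits(x, "laminitis_cohort")) {
    class(x) <- c("laminitis_cohort", class(x))
  }
  x
}

#' @export
print.laminitis_cohort <- function(x, ...) {
  cat(sprintf("Laminitis cohort: %d horses, %d visits, days %s\n",
              length(unique(x$horse_id)), nrow(x),
              paste(sort(unique(x$day)), collapse = ", ")))
  if (all(.sign_cols %in% names(x))) cat("  per-sign scores present\n")
  NextMethod()
}

#' Partition a cohort into fast and slow improvers
#'
#' Horses whose score at the partition day (day 14 by default) is at or
#' above the threshold (4 by default) are labelled slow improvers; the rest
#' fast. The default cut reproduces the observed separation in the clinical
#' cohort, where day-14 scores ran 0-3 in the fast group and 4-10 in the
#' slow group. Horses with no observation at the partition day are reported
#' unassigned.
#'
#' @param cohort long-format cohort data.
#' @param day partition day.
#' @param threshold minimum partition-day score for the slow group.
#' @return An object of class \code{"partition_result"}: \code{fast_ids},
#'   \code{slow_ids}, \code{unassigned_ids}, the partition day and
#'   threshold, and a per-group summary (n, median, min, max of the
#'   partition-day score).
#' @export
partition_fast_slow <- function(cohort, day = 14, threshold = 4) {
  cohort <- as_cohort(cohort)
  at <- cohort[cohort$day == day, , drop = FALSE]
  all_ids <- unique(cohort$horse_id)
  unassigned <- setdiff(all_ids, at$horse_id)
  slow <- at$horse_id[at$score >= threshold]
  fast <- at$horse_id[at$score < threshold]
  grp_summary <- function(ids) {
    s <- at$score[at$horse_id %in% ids]
    data.frame(n = length(ids),
               median = if (length(s)) stats::median(s) else NA_real_,
               min = if (length(s)) min(s) else NA_real_,
               max = if (length(s)) max(s) else NA_real_)
  }
  summ <- rbind(cbind(group = "fast", grp_summary(fast)),
                cbind(group = "slow", grp_summary(slow)))
  structure(list(fast_ids = fast, slow_ids = slow,
                 unassigned_ids = unassigned,
                 partition_day = day, threshold = threshold,
                 summary = summ),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("Partition at day %d (score >= %d -> slow): %d fast, %d slow%s\n",
              x$partition_day, x$threshold, length(x$fast_ids),
              length(x$slow_ids),
              if (length(x$unassigned_ids))
                sprintf(", %d unassigned", length(x$unassigned_ids)) else ""))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Per-day median trajectory of a cohort
#'
#' Median and interquartile range of the total score at each visit day
#' (midpoint convention for even n; quartiles by the inclusive convention of
#' \code{stats::quantile} type 7). If an \code{obel_grade} column is
#' present its per-day median is added.
#'
#' @param cohort long-format cohort data.
#' @return A data frame with one row per observed day: \code{day}, \code{n},
#'   \code{median}, \code{q1}, \code{q3} (and \code{median_obel} when
#'   available).
#' @export
median_trajectory <- function(cohort) {
  cohort <- as_cohort(cohort)
  days <- sort(unique(cohort$day))
  out <- do.call(rbind, lapply(days, function(d) {
    s <- cohort$score[cohort$day == d]
    data.frame(day = d, n = length(s), median = stats::median(s),
               q1 = unname(stats::quantile(s, 0.25)),
               q3 = unname(stats::quantile(s, 0.75)))
  }))
  if ("obel_grade" %in% names(cohort)) {
    out$median_obel <- vapply(days, function(d) {
      stats::median(cohort$obel_grade[cohort$day == d])
    }, numeric(1))
  }
  out
}

#' Per-sign summary table
#'
#' For each visit day and each of the five Meier criteria: the median points
#' and the percentage of horses with a positive score; plus, per sign, the
#' first day on which the median reaches 0 (the sign's median resolution
#' day).
#'
#' @param cohort a cohort with the five per-sign point columns (as produced
#'   by [allocate_signs()] or scored clinical data).
#' @return A list of class \code{"sign_summary"}: \code{medians} and
#'   \code{percent_positive} (day-by-sign data frames) and
#'   \code{resolution_day} (named vector; NA when the median never reaches
#'   0 within the observed days).
#' @export
sign_summary <- function(cohort) {
  cohort <- as_cohort(cohort)
  miss <- setdiff(.sign_cols, names(cohort))
  if (length(miss)) {
    stop("cohort lacks per-sign column(s): ", paste(miss, collapse = ", "),
         "; run allocate_signs() or provide scored exam data", call. = FALSE)
  }
  days <- sort(unique(cohort$day))
  med <- pct <- data.frame(day = days)
  for (sg in .sign_cols) {
    med[[sg]] <- vapply(days, function(d) {
      stats::median(cohort[[sg]][cohort$day == d])
    }, numeric(1))
    pct[[sg]] <- vapply(days, function(d) {
      100 * mean(cohort[[sg]][cohort$day == d] > 0)
    }, numeric(1))
  }
  resolution <- vapply(.sign_cols, function(sg) {
    hit <- days[med[[sg]] == 0]
    if (length(hit)) min(hit) else NA_real_
  }, numeric(1))
  structure(list(medians = med, percent_positive = pct,
                 resolution_day = resolution),
            class = "sign_summary")
}

#' @export
print.sign_summary <- function(x, ...) {
  cat("Per-sign median points by day:\n")
  print(x$medians, row.names = FALSE)
  cat("Percent of horses with a positive score:\n")
  print(round(x$percent_positive, 1), row.names = FALSE)
  cat("First day each sign's median reaches 0:\n")
  print(x$resolution_day)
  invisible(x)
}

#' Mann-Whitney U test (rank-sum with midrank ties)
#'
#' Computes the U statistic for the first group (number of pairs in which an
#' \code{a} value exceeds a \code{b} value, ties counting one half) and a
#' two-sided P value: by exhaustive enumeration of all group assignments
#' when both groups have at most \code{exact_max} observations, otherwise by
#' the normal approximation with the tie-corrected variance and a 0.5
#' continuity correction.
#'
#' @param group_a,group_b numeric score vectors (non-empty).
#' @param method \code{"auto"} (exact when both groups are small),
#'   \code{"exact"} or \code{"normal"}.
#' @param exact_max largest per-group size for which \code{"auto"} uses the
#'   exact enumeration.
#' @return A list with \code{U} (for \code{group_a}), \code{p_value}
#'   (two-sided) and \code{method}.
#' @export
mann_whitney_u <- function(group_a, group_b,
                           method = c("auto", "exact", "normal"),
                           exact_max = 8L) {
  method <- match.arg(method)
  if (!length(group_a) || !length(group_b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (anyNA(group_a) || anyNA(group_b)) stop("NA scores not allowed",
                                             call. = FALSE)
  na <- length(group_a); nb <- length(group_b)
  pooled <- c(group_a, group_b)
  rk <- rank(pooled)  # midranks
  Ua <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  if (method == "auto") {
    method <- if (na <= exact_max && nb <= exact_max) "exact" else "normal"
  }
  if (method == "exact") {
    # enumerate every assignment of na pooled values to group a
    combs <- utils::combn(na + nb, na)
    us <- colSums(matrix(rk[combs], nrow = na)) - na * (na + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(us <= Ua + eps), mean(us >= Ua - eps)))
  } else {
    mu <- na * nb / 2
    nt <- na + nb
    ties <- table(pooled)
    v <- na * nb / 12 * (nt + 1 - sum(ties^3 - ties) / (nt * (nt - 1)))
    if (v <= 0) {
      p <- 1
    } else {
      z <- (abs(Ua - mu) - 0.5) / sqrt(v)
      p <- 2 * stats::pnorm(-max(z, 0))
    }
  }
  list(U = Ua, p_value = min(p, 1), method = method)
}
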