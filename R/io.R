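# CSV/JSON input-output and the end-to-end pipeline.

#' Read a cohort from long-format CSV
#'
#' Expects a UTF-8 CSV with a header row and at least the columns
#' \code{horse_id}, \code{day}, \code{score}; optional per-sign point
#' columns, \code{group_label} and \code{obel_grade} are carried through.
#' Duplicate (horse, day) rows and, by default, scores outside the 0-12
#' Meier scale are rejected with named diagnostics.
#'
#' @param path CSV file path.
#' @param check_range reject scores outside [0, 12]?
#' @return A \code{"laminitis_cohort"} data frame.
#' @export
read_cohort_csv <- function(path, check_range = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("horse_id", "day", "score")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (!is.numeric(x$score)) stop("`score` column is not numeric", call. = FALSE)
  x$horse_id <- as.character(x$horse_id)
  as_cohort(x, check_range = check_range)
}

#' Write a cohort to long-format CSV
#'
#' @param cohort a cohort data frame.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  cohort <- as_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Score a table of Meier examinations
#'
#' Applies [score_meier()] (and, when the Obel observation columns are
#' present, [grade_obel()]) row by row to a data frame of per-visit clinical
#' observations, returning one scored row per visit.
#'
#' @param exams a data frame with columns \code{horse_id}, \code{day} and
#'   the seven [meier_exam()] level columns (lower-case strings); optional
#'   [obel_exam()] columns add an \code{obel_grade}.
#' @return A data frame: \code{horse_id}, \code{day}, the five per-criterion
#'   points, \code{total}, \code{circle_skipped} (and \code{obel_grade} if
#'   computable).
#' @export
score_exam_table <- function(exams) {
  stopifnot(is.data.frame(exams))
  need <- c("horse_id", "day", "weight_shifting", "foot_lift_left",
            "foot_lift_right", "gait_walk", "gait_circle", "pulse_left",
            "pulse_right")
  miss <- setdiff(need, names(exams))
  if (length(miss)) {
    stop("exam table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(exams)), function(i) {
    s <- score_meier(do.call(meier_exam, as.list(exams[i, need[-(1:2)]])))
    data.frame(horse_id = exams$horse_id[i], day = exams$day[i],
               weight_shifting_pts = s$weight_shifting_pts,
               foot_lift_pts = s$foot_lift_pts, walk_pts = s$walk_pts,
               circle_pts = s$circle_pts, pulse_pts = s$pulse_pts,
               total = s$total, circle_skipped = s$circle_skipped,
               stringsAsFactors = FALSE)
  }))
  obel_cols <- names(formals(obel_exam))
  if (all(obel_cols %in% names(exams))) {
    out$obel_grade <- vapply(seq_len(nrow(exams)), function(i) {
      grade_obel(do.call(obel_exam, as.list(exams[i, obel_cols])))
    }, integer(1))
  }
  out
}

.read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) stop("`config` must be a list or a YAML/JSON path",
                             call. = FALSE)
  config
}

#' Run the end-to-end analysis pipeline
#'
#' Executes simulate -> fit -> partition -> summarize -> report: simulates a
#' cohort (or reads one from \code{config$input}), fits the decay model by
#' SAEM, partitions fast/slow improvers, computes median-trajectory and
#' per-sign summaries, and writes the report bundle (cohort CSV, fit JSON,
#' partition CSV, summary CSVs, provenance JSON) to \code{config$out_dir}.
#' All randomness flows from \code{config$seed}, so rerunning an identical
#' config reproduces the bundle byte for byte. A stage failure aborts with
#' the failing stage named; outputs of completed stages are retained.
#'
#' @param config a named list (or path to a YAML/JSON file) with fields
#'   \code{n} (default 64), \code{days}, \code{params} (list of
#'   [population_params()] fields), \code{seed} (default 1),
#'   \code{slow_fraction} (default 0), \code{clip}, \code{round}
#'   (defaults TRUE), \code{signs} (default TRUE), \code{input} (optional
#'   cohort CSV; skips simulation), \code{error_model}, \code{fix_theta2},
#'   \code{saem} (list of [saem_settings()] fields), \code{fit} (default
#'   TRUE) and \code{out_dir} (default: no files written).
#' @return The report bundle (cohort, fit, partition, summaries, provenance),
#'   invisibly.
#' @export
run_pipeline <- function(config = list()) {
  config <- .read_config(config)
  cfg <- utils::modifyList(list(
    n = 64, days = c(0, 4, 9, 14, 25, 42), params = list(), seed = 1,
    slow_fraction = 0, clip = TRUE, round = TRUE, signs = TRUE,
    input = NULL, error_model = "additive", fix_theta2 = FALSE,
    saem = list(), fit = TRUE, out_dir = NULL), config)
  if (is.null(cfg$input) && !is_count(cfg$n)) {
    stop("invalid config: `n` must be a positive integer", call. = FALSE)
  }
  if (!is_count(cfg$seed, min = 0L)) {
    stop("invalid config: `seed` must be a non-negative integer", call. = FALSE)
  }
  pop <- as_population_params(
    utils::modifyList(as.list(population_params()), cfg$params))

  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(obj, file, writer) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, file))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  seeds <- derive_seeds(cfg$seed, 3L)

  cohort <- stage("simulate", {
    if (!is.null(cfg$input)) {
      read_cohort_csv(cfg$input)
    } else {
      simulate_cohort(pop, n = cfg$n, days = cfg$days, seed = seeds[1],
                      clip = cfg$clip, round_to_integer = cfg$round,
                      slow_fraction = cfg$slow_fraction, signs = cfg$signs)
    }
  })
  emit(cohort, "cohort.csv", write_cohort_csv)

  fit <- NULL
  if (isTRUE(cfg$fit)) {
    fit <- stage("fit", {
      st <- do.call(saem_settings,
                    utils::modifyList(list(seed = seeds[2]), cfg$saem))
      suppressWarnings(saem_fit(cohort, settings = st,
                                error_model = cfg$error_model,
                                fix_theta2 = cfg$fix_theta2))
    })
    emit(fit, "fit.json", function(obj, f) {
      jsonlite::write_json(list(
        estimates = unclass(obj$estimates),
        standard_errors = as.list(obj$standard_errors),
        cv_percent = as.list(obj$cv_percent),
        loglik = obj$loglik_estimate, loglik_mc_se = obj$loglik_mc_se,
        aic = obj$aic, k = obj$k, n_horses = obj$n_horses, n_obs = obj$n_obs,
        error_model = obj$error_model, converged = obj$converged,
        seed = seeds[2]), f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
    if (!is.null(out_dir)) {
      utils::write.csv(fit$predictions,
                       file.path(out_dir, "predictions.csv"),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(fit$convergence_trace),
                       file.path(out_dir, "convergence_trace.csv"),
                       row.names = FALSE)
    }
  }

  part <- stage("partition", partition_fast_slow(cohort))
  emit(part, "partition.csv", function(obj, f) {
    utils::write.csv(data.frame(
      horse_id = c(obj$fast_ids, obj$slow_ids, obj$unassigned_ids),
      group = rep(c("fast", "slow", "unassigned"),
                  c(length(obj$fast_ids), length(obj$slow_ids),
                    length(obj$unassigned_ids)))), f, row.names = FALSE)
  })

  medians <- stage("summarize", median_trajectory(cohort))
  emit(medians, "summary_medians.csv",
       function(obj, f) utils::write.csv(obj, f, row.names = FALSE))
  signs <- NULL
  if (all(.sign_cols %in% names(cohort))) {
    signs <- stage("summarize", sign_summary(cohort))
    emit(signs, "sign_summary.csv", function(obj, f) {
      utils::write.csv(merge(obj$medians, obj$percent_positive, by = "day",
                             suffixes = c("_median", "_pct_positive")),
                       f, row.names = FALSE)
    })
  }

  provenance <- list(config = cfg[setdiff(names(cfg), "out_dir")],
                     seed = cfg$seed, derived_seeds = seeds,
                     package = "laminitr",
                     package_version =
                       as.character(utils::packageVersion("laminitr")),
                     r_version = R.version.string)
  emit(provenance, "provenance.json", function(obj, f) {
    jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  invisible(list(cohort = cohort, fit = fit, partition = part,
                 medians = medians, signs = signs, provenance = provenance))
}
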