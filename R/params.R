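#' Population parameters of the laminitis recovery model
#'
#' Container for the fixed effects, between-horse variances and residual
#' standard deviation of the power-exponential decay model
#' \deqn{y_{ij} = \theta_{0i} \exp(-\theta_{1i} t_{ij}^{\theta_{2i}}) + \epsilon_{ij},}
#' where per horse \eqn{(\log\theta_{0i}, \log\theta_{1i}, \theta_{2i})'} is
#' multivariate normal with mean \code{(log_theta0, log_theta1, theta2)} and
#' diagonal covariance \code{diag(omega0, omega1, omega2)}, and
#' \eqn{\epsilon_{ij} \sim N(0, \sigma^2)}.
#'
#' Defaults are the published estimates for the fast-improvement group of a
#' clinical cohort of 64 horses scored with the 0-12 Meier method on days
#' 0, 4, 9, 14, 25 and 42 after diagnosis.
#'
#' @param log_theta0 log of the day-0 score (baseline severity).
#' @param log_theta1 log of the decay-rate parameter (1/day units before the
#'   power transform).
#' @param theta2 power on time; 1 gives plain exponential decay.
#' @param omega0,omega1,omega2 between-horse variances of
#'   \code{log_theta0}, \code{log_theta1} and \code{theta2} respectively.
#' @param sigma residual standard deviation, in score units.
#' @return An object of class \code{"population_params"}.
#' @examples
#' pop <- population_params()
#' exp(pop$log_theta0)  # model-predicted average day-0 score
#' @export
population_params <- function(log_theta0 = 2.07, log_theta1 = -1.95,
                              theta2 = 1.16,
                              omega0 = 0.025, omega1 = 0.361, omega2 = 0.087,
                              sigma = 0.99) {
  p <- list(log_theta0 = log_theta0, log_theta1 = log_theta1, theta2 = theta2,
            omega0 = omega0, omega1 = omega1, omega2 = omega2, sigma = sigma)
  for (nm in names(p)) {
    if (!(is.numeric(p[[nm]]) && length(p[[nm]]) == 1L && is.finite(p[[nm]]))) {
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
    }
  }
  if (p$omega0 < 0 || p$omega1 < 0 || p$omega2 < 0) {
    stop("random-effect variances `omega0`, `omega1`, `omega2` must be >= 0",
         call. = FALSE)
  }
  if (p$sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  structure(p, class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat("Population parameters of the laminitis decay model\n")
  cat(sprintf("  fixed effects: log theta0 = %.4g, log theta1 = %.4g, theta2 = %.4g\n",
              x$log_theta0, x$log_theta1, x$theta2))
  cat(sprintf("  random-effect variances: omega0 = %.4g, omega1 = %.4g, omega2 = %.4g\n",
              x$omega0, x$omega1, x$omega2))
  cat(sprintf("  residual SD: sigma = %.4g (score units)\n", x$sigma))
  cat(sprintf("  implied average day-0 score: %.2f\n", exp(x$log_theta0)))
  invisible(x)
}

# coerce a loosely specified list (e.g. from YAML/JSON config) to params
as_population_params <- function(x) {
  if (inherits(x, "population_params")) return(x)
  if (!is.list(x)) stop("cannot coerce to population_params", call. = FALSE)
  do.call(population_params, x[names(x) %in% names(formals(population_params))])
}

#' Assemble a table of per-horse individual effects
#'
#' @param horse_id identifiers (unique).
#' @param log_theta0_i,log_theta1_i,theta2_i per-horse realized parameters on
#'   the (log, log, natural) scales.
#' @return A data frame of class \code{"individual_effects"} with one row per
#'   horse.
#' @export
individual_effects <- function(horse_id, log_theta0_i, log_theta1_i, theta2_i) {
  n <- length(horse_id)
  stopifnot(length(log_theta0_i) == n, length(log_theta1_i) == n,
            length(theta2_i) == n)
  if (anyDuplicated(horse_id)) stop("duplicate `horse_id`", call. = FALSE)
  vals <- cbind(log_theta0_i, log_theta1_i, theta2_i)
  if (!all(is.finite(vals))) stop("individual effects must be finite", call. = FALSE)
  structure(
    data.frame(horse_id = as.character(horse_id),
               log_theta0_i = as.numeric(log_theta0_i),
               log_theta1_i = as.numeric(log_theta1_i),
               theta2_i = as.numeric(theta2_i),
               stringsAsFactors = FALSE),
    class = c("individual_effects", "data.frame"))
}
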