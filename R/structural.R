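# Structural model and complete-data likelihood of the decay NLME.

#' Structural mean of the decay model
#'
#' Evaluates \eqn{f(t) = \theta_{0i}\exp(-\theta_{1i} t^{\theta_{2i}})} with
#' \eqn{\theta_{0i} = \exp(\log\theta_{0i})} and
#' \eqn{\theta_{1i} = \exp(\log\theta_{1i})}. At \eqn{t = 0} the convention
#' \eqn{0^{\theta_2} = 0} is used, so the day-0 mean equals
#' \eqn{\theta_{0i}} exactly.
#'
#' @param effects a one-row [individual_effects()] data frame, or any list
#'   with elements \code{log_theta0_i}, \code{log_theta1_i}, \code{theta2_i}.
#' @param t vector of non-negative times (days).
#' @return The structural mean at each \code{t}, in score units.
#' @examples
#' eff <- individual_effects("pop", 2.07, -1.95, 1.16)
#' structural_mean(eff, 0)   # 7.92: model-average day-0 score
#' structural_mean(eff, 25)  # ~0.02
#' @export
structural_mean <- function(effects, t) {
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  .struct_f(effects$log_theta0_i, effects$log_theta1_i, effects$theta2_i, t)
}

# vectorized over matched-length parameter/time vectors (recycled as needed)
.struct_f <- function(l0, l1, t2, t) {
  tp <- t^t2
  tp[t == 0] <- 0  # 0^theta2 := 0 even for theta2 <= 0 proposals
  exp(l0) * exp(-exp(l1) * tp)
}

#' Complete-data log-likelihood of the hierarchical model
#'
#' Sum of the Gaussian residual log-density over all observations plus the
#' Gaussian random-effect log-density over horses. The residual SD is
#' \code{sigma} under the additive error model and
#' \eqn{a + b\,|f|} under the combined (additive plus proportional) model,
#' where \eqn{f} is the structural mean. Random-effect components with zero
#' variance must have the individual value pinned to the population value.
#'
#' @param pop a [population_params()].
#' @param effects an [individual_effects()] table covering every horse in
#'   \code{cohort}.
#' @param cohort a long-format cohort (\code{horse_id}, \code{day},
#'   \code{score}).
#' @param error_model \code{"additive"} or \code{"combined"}.
#' @param a,b combined-error coefficients (intercept SD and proportional
#'   slope); under \code{"additive"}, \code{a} defaults to \code{pop$sigma}
#'   and \code{b} to 0.
#' @return The scalar complete-data log-likelihood.
#' @export
complete_data_loglik <- function(pop, effects, cohort,
                                 error_model = c("additive", "combined"),
                                 a = NULL, b = NULL) {
  pop <- as_population_params(pop)
  error_model <- match.arg(error_model)
  cohort <- as_cohort(cohort)
  if (is.null(a)) a <- pop$sigma
  if (is.null(b)) b <- 0
  if (a <= 0 || b < 0) {
    stop("error coefficients must satisfy a > 0, b >= 0", call. = FALSE)
  }
  idx <- match(cohort$horse_id, effects$horse_id)
  if (anyNA(idx)) stop("every observed horse needs individual effects",
                       call. = FALSE)
  f <- .struct_f(effects$log_theta0_i[idx], effects$log_theta1_i[idx],
                 effects$theta2_i[idx], cohort$day)
  sd_res <- if (error_model == "additive") a else a + b * abs(f)
  ll <- sum(dnorm(cohort$score, f, sd_res, log = TRUE))
  # random-effect density; zero-variance components contribute 0 iff pinned
  psi <- cbind(effects$log_theta0_i, effects$log_theta1_i, effects$theta2_i)
  mu <- c(pop$log_theta0, pop$log_theta1, pop$theta2)
  om <- c(pop$omega0, pop$omega1, pop$omega2)
  for (j in 1:3) {
    if (om[j] > 0) {
      ll <- ll + sum(dnorm(psi[, j], mu[j], sqrt(om[j]), log = TRUE))
    } else if (any(psi[, j] != mu[j])) {
      stop("zero-variance random effect with non-degenerate individual values",
           call. = FALSE)
    }
  }
  ll
}
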