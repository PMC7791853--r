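# Stochastic approximation EM for the power-exponential decay NLME.
#
# The complete-data model is exponential-family in the individual parameters
# psi_i = (log theta0_i, log theta1_i, theta2_i), so SAEM alternates:
#   (S)  Metropolis-Hastings draws of each horse's psi_i from its conditional
#        posterior given the data and current population parameters;
#   (SA) stochastic-approximation smoothing of the sufficient statistics
#        (sums and squared sums of psi, residual sum of squares) with step
#        sizes gamma_k = 1 during burn-in and 1/(k - k_burnin) afterwards;
#   (M)  closed-form updates: fixed effects = smoothed means, variances =
#        smoothed central second moments, sigma^2 = smoothed RSS / N.
# Standard errors come from the observed Fisher information (Louis'
# identity), averaged in a post-estimation conditional sampling phase with
# the estimates frozen; the score-variance term is accumulated per horse,
# which the independence of horses permits and which removes the noisy
# cross-horse products of the naive estimator.

#' SAEM algorithm settings
#'
#' @param n_burnin_iterations iterations with step size 1 (exploration).
#' @param n_smoothing_iterations iterations with decaying step size
#'   \eqn{\gamma_k = 1/(k - k_{burnin})} (averaging).
#' @param mcmc_steps_per_iteration Metropolis-Hastings transition kernels per
#'   SAEM iteration (each kernel sweeps the free components of
#'   \eqn{\psi_i}).
#' @param seed RNG seed for the whole fit.
#' @param proposal_scale initial random-walk proposal SDs for
#'   \eqn{(\log\theta_{0i}, \log\theta_{1i}, \theta_{2i})}; adapted during
#'   burn-in toward a ~40\% acceptance rate.
#' @param n_fisher_iterations Metropolis-Hastings iterations of the
#'   post-estimation phase that, holding the final estimates fixed,
#'   averages the conditional score and Hessian for the Fisher-information
#'   standard errors and the conditional moments used by the
#'   importance-sampling log-likelihood proposal.
#' @param convergence_tolerance maximum relative drift of any parameter over
#'   the second half of the smoothing phase before a non-convergence warning
#'   is raised.
#' @param variance_floor lower bound applied to variance estimates for
#'   numerical stability.
#' @return A list of class \code{"saem_settings"}.
#' @export
saem_settings <- function(n_burnin_iterations = 300,
                          n_smoothing_iterations = 100,
                          mcmc_steps_per_iteration = 5,
                          n_fisher_iterations = 300,
                          seed = NULL,
                          proposal_scale = c(0.15, 0.45, 0.25),
                          convergence_tolerance = 0.1,
                          variance_floor = 1e-6) {
  stopifnot(is_count(n_burnin_iterations), is_count(n_smoothing_iterations),
            is_count(mcmc_steps_per_iteration), is_count(n_fisher_iterations),
            length(proposal_scale) == 3L, all(proposal_scale > 0),
            convergence_tolerance > 0, variance_floor > 0)
  structure(list(n_burnin_iterations = as.integer(n_burnin_iterations),
                 n_smoothing_iterations = as.integer(n_smoothing_iterations),
                 mcmc_steps_per_iteration = as.integer(mcmc_steps_per_iteration),
                 n_fisher_iterations = as.integer(n_fisher_iterations),
                 seed = seed, proposal_scale = proposal_scale,
                 convergence_tolerance = convergence_tolerance,
                 variance_floor = variance_floor),
            class = "saem_settings")
}

# moment-based fallback initial values
.moment_init <- function(cohort) {
  d0 <- cohort$score[cohort$day == min(cohort$day)]
  m0 <- max(mean(d0), 0.5)
  # crude decay rate: first day the mean score halves
  mday <- tapply(cohort$score, cohort$day, mean)
  days <- as.numeric(names(mday))
  half <- days[which(mday <= m0 / 2)[1]]
  rate <- if (is.na(half) || half <= 0) 0.05 else log(2) / half
  population_params(log_theta0 = log(m0), log_theta1 = log(rate), theta2 = 1,
                    omega0 = 0.05, omega1 = 0.2, omega2 = 0.05, sigma = 1)
}

.saem_init <- function(cohort, init) {
  if (!is.null(init)) return(as_population_params(init))
  fit <- tryCatch(suppressWarnings(oracle_fit_two_stage(cohort)),
                  error = function(e) NULL)
  if (!is.null(fit) && all(is.finite(unlist(fit)))) return(fit)
  .moment_init(cohort)
}

#' Fit the decay model by SAEM
#'
#' Maximum-likelihood estimation of the nonlinear mixed-effects model
#' \eqn{y_{ij} = \theta_{0i}\exp(-\theta_{1i} t_{ij}^{\theta_{2i}}) +
#' \epsilon_{ij}} with independent normal random effects on
#' \eqn{(\log\theta_{0i}, \log\theta_{1i}, \theta_{2i})} and additive (or
#' additive plus proportional, SD \eqn{= a + b|f|}) residual error. Scores
#' are treated as continuous. After estimation a post-run conditional
#' sampling phase computes standard errors from the observed Fisher
#' information (Louis' identity with per-horse score variances), CV\%
#' (\eqn{100\,SE/|estimate|}), an importance-sampling estimate of the
#' marginal log-likelihood, and the AIC.
#'
#' @param cohort long-format cohort data (\code{horse_id}, \code{day},
#'   \code{score}); at least 2 horses with 2 visits each and non-constant
#'   scores.
#' @param init optional [population_params()] initial values; by default a
#'   two-stage nonlinear least-squares fit ([oracle_fit_two_stage()]) seeds
#'   the run, falling back to moment-based values.
#' @param settings a [saem_settings()].
#' @param error_model \code{"additive"} (default; residual SD \code{sigma})
#'   or \code{"combined"} (SD \eqn{a + b|f|}).
#' @param fix_theta2 fix the power on time at 1 (plain exponential decay,
#'   no \eqn{\theta_2} random effect)? Used for AIC model comparison.
#' @param loglik_samples importance-sampling draws per horse for the
#'   log-likelihood estimate.
#' @return An object of class \code{"saem_fit"}; see
#'   \code{print.saem_fit} and [fit_diagnostics()].
#' @export
saem_fit <- function(cohort, init = NULL, settings = saem_settings(),
                     error_model = c("additive", "combined"),
                     fix_theta2 = FALSE, loglik_samples = 1000) {
  error_model <- match.arg(error_model)
  stop_if_not_flag(fix_theta2, "fix_theta2")
  cohort <- as_cohort(cohort)
  ids <- unique(cohort$horse_id)
  n <- length(ids)
  if (n < 2L) stop("degenerate cohort: need at least 2 horses", call. = FALSE)
  nv <- table(cohort$horse_id)
  if (any(nv < 2L)) stop("degenerate cohort: every horse needs >= 2 visits",
                         call. = FALSE)
  if (stats::sd(cohort$score) == 0) {
    stop("degenerate cohort: scores are constant", call. = FALSE)
  }
  id <- match(cohort$horse_id, ids)
  y <- as.numeric(cohort$score)
  t <- as.numeric(cohort$day)
  N <- length(y)

  pop0 <- .saem_init(cohort, init)
  free <- if (fix_theta2) c(1L, 2L) else c(1L, 2L, 3L)
  theta <- c(pop0$log_theta0, pop0$log_theta1,
             if (fix_theta2) 1 else pop0$theta2)
  omega <- pmax(c(pop0$omega0, pop0$omega1, pop0$omega2),
                settings$variance_floor)
  if (fix_theta2) omega[3] <- 0
  sigma2 <- pop0$sigma^2
  ab <- c(a = pop0$sigma, b = 0.1)  # combined-error coefficients

  B <- settings$n_burnin_iterations
  S <- settings$n_smoothing_iterations
  vfloor <- settings$variance_floor
  sc <- settings$proposal_scale

  psi <- matrix(theta, nrow = n, ncol = 3, byrow = TRUE)

  res_sd <- function(f) {
    if (error_model == "additive") sqrt(sigma2) else ab[1] + ab[2] * abs(f)
  }
  ll_ind <- function(p) {
    f <- .struct_f(p[id, 1], p[id, 2], p[id, 3], t)
    as.numeric(rowsum(dnorm(y, f, res_sd(f), log = TRUE), id))
  }

  # SA accumulators
  ss1 <- colSums(psi)          # sum psi
  ss2 <- colSums(psi^2)        # sum psi^2
  f_cur <- .struct_f(psi[id, 1], psi[id, 2], psi[id, 3], t)
  ss_r2 <- (y - f_cur)^2       # per-obs squared residual (smoothed)
  ss_af <- abs(f_cur)          # per-obs |f| (smoothed, combined model)

  p_names <- c(c("log_theta0", "log_theta1", "theta2")[free],
               c("omega0", "omega1", "omega2")[free],
               if (error_model == "additive") "sigma2" else c("a", "b"))
  p_len <- length(p_names)
  Sbar <- matrix(0, n, p_len)        # E[s_i | y] per horse
  CPbar <- matrix(0, p_len, p_len)   # E[sum_i s_i s_i' | y]
  Hbar <- matrix(0, p_len, p_len)    # E[complete-data Hessian | y]

  trace <- matrix(NA_real_, B + S, p_len,
                  dimnames = list(NULL, p_names))
  acc_count <- acc_tot <- numeric(3)
  n_theta2_nonpos <- 0L
  n_theta2_draws <- 0L
  post_m <- psi
  post_v <- matrix(1, n, 3)

  with_seed(settings$seed, {
    llc <- ll_ind(psi)
    for (k in seq_len(B + S)) {
      gamma <- if (k <= B) 1 else 1 / (k - B)
      ## --- S: Metropolis-Hastings over free components ---
      for (m in seq_len(settings$mcmc_steps_per_iteration)) {
        for (j in free) {
          prop <- psi
          prop[, j] <- prop[, j] + rnorm(n, 0, sc[j])
          llp <- ll_ind(prop)
          logr <- llp - llc +
            dnorm(prop[, j], theta[j], sqrt(omega[j]), log = TRUE) -
            dnorm(psi[, j], theta[j], sqrt(omega[j]), log = TRUE)
          acc <- log(runif(n)) < logr
          psi[acc, j] <- prop[acc, j]
          llc[acc] <- llp[acc]
          acc_count[j] <- acc_count[j] + sum(acc)
          acc_tot[j] <- acc_tot[j] + n
        }
      }
      # adapt proposal scales during burn-in
      if (k <= B && k %% 25 == 0) {
        rate <- ifelse(acc_tot > 0, acc_count / acc_tot, 0.4)
        sc <- sc * ifelse(rate < 0.25, 0.7, ifelse(rate > 0.55, 1.4, 1))
        acc_count[] <- acc_tot[] <- 0
      }
      ## --- SA: smooth the sufficient statistics ---
      f_cur <- .struct_f(psi[id, 1], psi[id, 2], psi[id, 3], t)
      ss1 <- ss1 + gamma * (colSums(psi) - ss1)
      ss2 <- ss2 + gamma * (colSums(psi^2) - ss2)
      ss_r2 <- ss_r2 + gamma * ((y - f_cur)^2 - ss_r2)
      ss_af <- ss_af + gamma * (abs(f_cur) - ss_af)
      ## --- M: closed-form (or profile) updates ---
      theta[free] <- ss1[free] / n
      om_new <- pmax(ss2[free] / n - theta[free]^2, vfloor)
      if (k <= B) om_new <- pmax(om_new, 0.95 * omega[free])  # annealing
      omega[free] <- om_new
      if (error_model == "additive") {
        s2_new <- sum(ss_r2) / N
        if (k <= B) s2_new <- max(s2_new, 0.95 * sigma2)
        sigma2 <- max(s2_new, vfloor)
      } else {
        obj <- function(par) {
          g <- par[1] + par[2] * ss_af
          sum(log(g) + ss_r2 / (2 * g^2))
        }
        opt <- stats::optim(ab, obj, method = "L-BFGS-B",
                            lower = c(1e-4, 0), upper = c(Inf, Inf))
        ab <- opt$par
      }
      llc <- ll_ind(psi)  # parameters moved; refresh cached conditionals

      trace[k, ] <- c(theta[free], omega[free],
                      if (error_model == "additive") sigma2 else ab)
    }

    ## --- post-estimation phase: with the estimates frozen, sample the
    ## conditional posterior of the individual parameters and average the
    ## complete-data score/Hessian (Louis' identity for the observed Fisher
    ## information) and the conditional moments used downstream ---
    nF <- settings$n_fisher_iterations
    post_m[] <- 0; post_v[] <- 0
    for (k in seq_len(nF)) {
      for (m in seq_len(settings$mcmc_steps_per_iteration)) {
        for (j in free) {
          prop <- psi
          prop[, j] <- prop[, j] + rnorm(n, 0, sc[j])
          llp <- ll_ind(prop)
          logr <- llp - llc +
            dnorm(prop[, j], theta[j], sqrt(omega[j]), log = TRUE) -
            dnorm(psi[, j], theta[j], sqrt(omega[j]), log = TRUE)
          acc <- log(runif(n)) < logr
          psi[acc, j] <- prop[acc, j]
          llc[acc] <- llp[acc]
        }
      }
      f_cur <- .struct_f(psi[id, 1], psi[id, 2], psi[id, 3], t)
      post_m <- post_m + (psi - post_m) / k
      post_v <- post_v + (psi^2 - post_v) / k
      n_theta2_nonpos <- n_theta2_nonpos + sum(psi[, 3] <= 0)
      n_theta2_draws <- n_theta2_draws + n
      sh <- .louis_score_hess(psi, y, f_cur, id, theta, omega, sigma2, ab,
                              free, error_model)
      Sbar <- Sbar + (sh$score_by_horse - Sbar) / k
      CPbar <- CPbar + (crossprod(sh$score_by_horse) - CPbar) / k
      Hbar <- Hbar + (sh$hess - Hbar) / k
    }

    ## assemble results -----------------------------------------------------
    sigma_hat <- if (error_model == "additive") sqrt(sigma2) else ab[1]
    est_pop <- population_params(
      log_theta0 = theta[1], log_theta1 = theta[2], theta2 = theta[3],
      omega0 = omega[1], omega1 = omega[2],
      omega2 = if (fix_theta2) 0 else omega[3],
      sigma = sigma_hat)

    # Louis' identity with horses independent:
    # I_obs = -E[H | y] - sum_i Var(s_i | y)
    info <- -Hbar - (CPbar - crossprod(Sbar))
    info <- (info + t(info)) / 2
    dimnames(info) <- list(p_names, p_names)
    se_eta <- rep(NA_real_, p_len)
    cov_eta <- tryCatch(solve(info), error = function(e) NULL)
    if (!is.null(cov_eta)) {
      dg <- diag(cov_eta)
      se_eta[dg > 0] <- sqrt(dg[dg > 0])
      if (any(dg <= 0)) {
        warning("observed information too weak for: ",
                paste(p_names[dg <= 0], collapse = ", "),
                "; their standard errors are NA (increase ",
                "`n_fisher_iterations` or expect a poorly identified variance)")
      }
    } else {
      warning("Fisher information not invertible; standard errors are NA")
    }
    names(se_eta) <- p_names
    se <- se_eta
    if (error_model == "additive") {
      # report on the sigma scale (delta method from sigma^2)
      se["sigma2"] <- se["sigma2"] / (2 * sigma_hat)
      names(se)[names(se) == "sigma2"] <- "sigma"
    }
    est_vec <- c(theta[free], omega[free],
                 if (error_model == "additive") sigma_hat else ab)
    names(est_vec) <- names(se)
    cv <- 100 * se / abs(est_vec)

    post_var <- pmax(post_v - post_m^2, 1e-8)
    post_eff <- individual_effects(ids, post_m[, 1], post_m[, 2], post_m[, 3])

    conv <- .saem_convergence(trace, B, S, settings$convergence_tolerance)

    fit <- structure(list(
      estimates = est_pop,
      estimate_vector = est_vec,
      standard_errors = se,
      cv_percent = cv,
      n_horses = n, n_obs = N,
      k = p_len,
      error_model = error_model,
      error_coefficients = if (error_model == "combined") ab else NULL,
      fix_theta2 = fix_theta2,
      individual_effects_posterior_means = post_eff,
      posterior_variances = post_var,
      frac_theta2_nonpositive = n_theta2_nonpos / max(n_theta2_draws, 1L),
      information = info,
      convergence_trace = trace,
      converged = conv$converged,
      max_relative_drift = conv$drift,
      settings = settings,
      loglik_estimate = NA_real_, loglik_mc_se = NA_real_, aic = NA_real_
    ), class = "saem_fit")
    if (!conv$converged) {
      warning(sprintf(
        "SAEM may not have converged (max relative parameter drift %.3f over the smoothing phase); inspect `convergence_trace`",
        conv$drift))
    }

    ## predictions / residuals (individual = posterior-mean psi)
    f_pop <- .struct_f(theta[1], theta[2], theta[3], t)
    f_ind <- .struct_f(post_m[id, 1], post_m[id, 2], post_m[id, 3], t)
    fit$predictions <- data.frame(
      horse_id = cohort$horse_id, day = cohort$day, observed = y,
      population_prediction = f_pop, individual_prediction = f_ind,
      residual = y - f_ind,
      standardized_residual = (y - f_ind) /
        (if (error_model == "additive") sigma_hat else ab[1] + ab[2] * abs(f_ind)),
      stringsAsFactors = FALSE)

    ll <- estimate_loglik(fit, cohort, n_importance_samples = loglik_samples,
                          seed = sample.int(.Machine$integer.max - 1L, 1))
    fit$loglik_estimate <- as.numeric(ll)
    fit$loglik_mc_se <- attr(ll, "mc_se")
    fit$aic <- -2 * fit$loglik_estimate + 2 * fit$k
    fit
  })
}

.saem_convergence <- function(trace, B, S, tol) {
  sm <- trace[(B + 1):(B + S), , drop = FALSE]
  h <- floor(S / 2)
  m1 <- colMeans(sm[seq_len(h), , drop = FALSE])
  m2 <- colMeans(sm[(S - h + 1):S, , drop = FALSE])
  drift <- max(abs(m2 - m1) / pmax(abs(m2), 0.05))
  list(converged = drift < tol, drift = drift)
}

# Analytic per-horse score and total Hessian of the complete-data
# log-likelihood in eta = (theta_free, omega_free, sigma2 | a, b); blocks
# are diagonal in the complete-data Hessian except for theta/omega pairs.
# The score is returned horse by horse so that the Louis variance can be
# accumulated per horse (horses are independent, so the cross-horse terms
# of Var(score) are exactly zero and need not be estimated).
.louis_score_hess <- function(psi, y, f, id, theta, omega, sigma2, ab, free,
                              error_model) {
  n <- nrow(psi)
  nf <- length(free)
  p_len <- 2 * nf + if (error_model == "additive") 1L else 2L
  S <- matrix(0, n, p_len)
  H <- matrix(0, p_len, p_len)
  for (jj in seq_along(free)) {
    j <- free[jj]
    d <- psi[, j] - theta[j]
    w <- omega[j]
    S[, jj] <- d / w
    S[, nf + jj] <- d^2 / (2 * w^2) - 1 / (2 * w)
    H[jj, jj] <- -n / w
    H[jj, nf + jj] <- H[nf + jj, jj] <- -sum(d) / w^2
    H[nf + jj, nf + jj] <- -sum(d^2) / w^3 + n / (2 * w^2)
  }
  r <- y - f
  if (error_model == "additive") {
    v <- sigma2
    S[, p_len] <- as.numeric(rowsum(r^2 / (2 * v^2) - 1 / (2 * v), id))
    H[p_len, p_len] <- -sum(r^2) / v^3 + length(y) / (2 * v^2)
  } else {
    g <- ab[1] + ab[2] * abs(f)
    dg <- -1 / g + r^2 / g^3
    d2g <- 1 / g^2 - 3 * r^2 / g^4
    ia <- p_len - 1L; ib <- p_len
    S[, ia] <- as.numeric(rowsum(dg, id))
    S[, ib] <- as.numeric(rowsum(abs(f) * dg, id))
    H[ia, ia] <- sum(d2g)
    H[ia, ib] <- H[ib, ia] <- sum(abs(f) * d2g)
    H[ib, ib] <- sum(f^2 * d2g)
  }
  list(score_by_horse = S, hess = H)
}

#' @export
print.saem_fit <- function(x, ...) {
  cat(sprintf("SAEM fit of the decay NLME (%s error%s)\n", x$error_model,
              if (x$fix_theta2) ", theta2 fixed at 1" else ""))
  cat(sprintf("  %d horses, %d observations, %d estimated parameters\n",
              x$n_horses, x$n_obs, x$k))
  tab <- data.frame(Estimate = x$estimate_vector,
                    SE = x$standard_errors,
                    `CV%` = round(x$cv_percent, 1), check.names = FALSE)
  print(round(tab, 4))
  cat(sprintf("  log-likelihood %.2f (MC SE %.3f), AIC %.2f\n",
              x$loglik_estimate, x$loglik_mc_se, x$aic))
  if (!x$converged) cat("  WARNING: convergence drift above tolerance\n")
  invisible(x)
}

#' @export
summary.saem_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  fraction of posterior theta2 draws <= 0: %.4f\n",
              object$frac_theta2_nonpositive))
  invisible(object)
}
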