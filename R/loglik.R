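# Importance-sampling marginal log-likelihood and AIC model comparison.

#' Importance-sampling estimate of the marginal log-likelihood
#'
#' Integrates the random effects out of the likelihood horse by horse using
#' importance sampling with an independent Gaussian proposal centred at each
#' horse's conditional posterior mean with its posterior variances (both
#' accumulated during the SAEM smoothing phase). When all random-effect
#' variances are (numerically) zero the marginal likelihood is available in
#' closed form and is returned exactly.
#'
#' @param fit a converged [saem_fit()].
#' @param cohort the cohort the model was fitted to.
#' @param n_importance_samples Monte-Carlo draws per horse.
#' @param seed RNG seed.
#' @return The scalar log-likelihood estimate, with the Monte-Carlo standard
#'   error attached as attribute \code{"mc_se"} (0 for the closed form).
#' @export
estimate_loglik <- function(fit, cohort, n_importance_samples = 1000,
                            seed = NULL) {
  stopifnot(inherits(fit, "saem_fit"))
  if (!is_count(n_importance_samples)) {
    stop("`n_importance_samples` must be a positive integer", call. = FALSE)
  }
  cohort <- as_cohort(cohort)
  pop <- fit$estimates
  ab <- fit$error_coefficients
  res_sd_fun <- function(f) {
    if (fit$error_model == "additive") pop$sigma else ab[1] + ab[2] * abs(f)
  }
  mu <- c(pop$log_theta0, pop$log_theta1, pop$theta2)
  om <- c(pop$omega0, pop$omega1, pop$omega2)
  # variances at (or within a whisker of) the estimation floor are treated
  # as zero: those random effects have collapsed out of the model
  floor_tol <- 10 * (if (!is.null(fit$settings)) fit$settings$variance_floor
                     else 1e-6)
  free <- which(om > floor_tol)

  ids <- unique(cohort$horse_id)
  if (length(free) == 0L) {
    # no random effects left: plain fixed-effects Gaussian likelihood
    f <- .struct_f(mu[1], mu[2], mu[3], cohort$day)
    ll <- sum(dnorm(cohort$score, f, res_sd_fun(f), log = TRUE))
    return(structure(ll, mc_se = 0))
  }

  pm <- fit$individual_effects_posterior_means
  pv <- fit$posterior_variances
  M <- as.integer(n_importance_samples)
  with_seed(seed, {
    ll_i <- se2_i <- numeric(length(ids))
    for (h in seq_along(ids)) {
      rows <- cohort$horse_id == ids[h]
      yh <- cohort$score[rows]; th <- cohort$day[rows]
      hi <- match(ids[h], pm$horse_id)
      m_h <- c(pm$log_theta0_i[hi], pm$log_theta1_i[hi], pm$theta2_i[hi])
      v_h <- pmax(pv[hi, ], 1e-6)
      psi <- matrix(mu, M, 3, byrow = TRUE)
      logq <- numeric(M)
      for (j in free) {
        draw <- rnorm(M, m_h[j], sqrt(v_h[j]))
        psi[, j] <- draw
        logq <- logq + dnorm(draw, m_h[j], sqrt(v_h[j]), log = TRUE)
      }
      f <- .struct_f(rep(psi[, 1], each = length(th)),
                     rep(psi[, 2], each = length(th)),
                     rep(psi[, 3], each = length(th)),
                     rep(th, times = M))
      lly <- colSums(matrix(dnorm(rep(yh, times = M), f, res_sd_fun(f),
                                  log = TRUE), nrow = length(th)))
      logp <- numeric(M)
      for (j in free) {
        logp <- logp + dnorm(psi[, j], mu[j], sqrt(om[j]), log = TRUE)
      }
      lw <- lly + logp - logq
      mx <- max(lw)
      w <- exp(lw - mx)
      ll_i[h] <- mx + log(mean(w))
      # delta-method MC variance of log-mean-weight
      se2_i[h] <- stats::var(w) / (M * mean(w)^2)
    }
    structure(sum(ll_i), mc_se = sqrt(sum(se2_i)))
  })
}

#' Compare candidate model configurations by AIC
#'
#' Fits each candidate configuration (e.g. the power on time fixed at 1
#' versus free; additive versus combined residual error) to the same cohort
#' and tabulates log-likelihood and AIC, ranked best-first. Candidates whose
#' fit fails are reported with \code{ok = FALSE} and excluded from the
#' ranking.
#'
#' @param cohort long-format cohort data.
#' @param candidates a list of configurations, each a list with elements
#'   \code{fix_theta2} (default \code{FALSE}) and \code{error_model}
#'   (default \code{"additive"}).
#' @param settings a [saem_settings()] shared by all candidates.
#' @param init optional shared initial values.
#' @return A data frame with one row per candidate: configuration, number of
#'   parameters \code{k}, \code{loglik}, \code{aic}, \code{converged},
#'   \code{ok} and \code{rank} (NA for failed fits), sorted by AIC. The
#'   fitted objects are attached as attribute \code{"fits"}.
#' @export
compare_models <- function(cohort, candidates, settings = saem_settings(),
                           init = NULL) {
  stopifnot(is.list(candidates), length(candidates) >= 1L)
  rows <- vector("list", length(candidates))
  fits <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    cf <- candidates[[i]]
    fx <- isTRUE(cf$fix_theta2)
    em <- if (is.null(cf$error_model)) "additive" else cf$error_model
    fit <- tryCatch(
      suppressWarnings(saem_fit(cohort, init = init, settings = settings,
                                error_model = em, fix_theta2 = fx)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[i]] <- data.frame(model = i, fix_theta2 = fx, error_model = em,
                              k = NA_integer_, loglik = NA_real_,
                              aic = NA_real_, converged = NA, ok = FALSE)
    } else {
      fits[[i]] <- fit
      rows[[i]] <- data.frame(model = i, fix_theta2 = fx, error_model = em,
                              k = fit$k, loglik = fit$loglik_estimate,
                              aic = fit$aic, converged = fit$converged,
                              ok = TRUE)
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(!tab$ok, tab$aic), , drop = FALSE]
  tab$rank <- ifelse(tab$ok, cumsum(tab$ok), NA_integer_)
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}

#' Residual and observed-versus-predicted diagnostics
#'
#' Per-observation population predictions (fixed effects only), individual
#' predictions (posterior-mean random effects), raw and standardized
#' residuals, plus a check for the known zero-floor limitation: because
#' clinical scores cannot go below 0, observations recorded as 0 sit
#' systematically below their model predictions late in recovery. The mean
#' of (prediction - observation) over zero-score visits is reported and
#' flagged when it exceeds twice its standard error.
#'
#' @param fit a [saem_fit()].
#' @param cohort optional cohort (defaults to the fitted data stored in the
#'   fit's prediction table).
#' @return The prediction/residual data frame, with a list attribute
#'   \code{"zero_score_bias"} (\code{n}, \code{mean_bias}, \code{se},
#'   \code{flagged}).
#' @export
fit_diagnostics <- function(fit, cohort = NULL) {
  stopifnot(inherits(fit, "saem_fit"))
  tab <- fit$predictions
  if (!is.null(cohort)) {
    cohort <- as_cohort(cohort)
    key_fit <- paste(tab$horse_id, tab$day)
    key_new <- paste(cohort$horse_id, cohort$day)
    if (!setequal(key_fit, key_new)) {
      stop("`cohort` does not match the data the model was fitted to",
           call. = FALSE)
    }
  }
  zero <- tab$observed == 0
  bias <- tab$individual_prediction[zero] - tab$observed[zero]
  zb <- if (sum(zero) >= 2L) {
    se <- stats::sd(bias) / sqrt(length(bias))
    list(n = sum(zero), mean_bias = mean(bias), se = se,
         flagged = is.finite(se) && se > 0 && mean(bias) > 2 * se)
  } else if (sum(zero) == 1L) {
    list(n = 1L, mean_bias = bias, se = NA_real_, flagged = FALSE)
  } else {
    list(n = 0L, mean_bias = NA_real_, se = NA_real_, flagged = FALSE)
  }
  attr(tab, "zero_score_bias") <- zb
  tab
}
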