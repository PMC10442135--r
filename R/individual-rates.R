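# Per-subject growth-rate estimation given fitted population parameters.

# Conditional log-likelihood of one subject's increment series given lambda
# (vectorised over lambda).
subject_cond_loglik <- function(dt, dz, lambda, sigma_w, sigma_m) {
  n <- length(dt)
  S <- subject_covariance(dt, sigma_w, sigma_m)
  L <- t(chol(S))
  logdet <- sum(log(diag(L)))
  R <- outer(dt, lambda - sigma_w^2 / 2)
  R <- dz - R
  U <- forwardsolve(L, R)
  q <- colSums(U^2)
  -0.5 * q - logdet - n / 2 * log(2 * pi)
}

# Rate estimate for one internal series element.
individual_rate_series <- function(s, params, mode = c("map", "conditional_ml")) {
  mode <- match.arg(mode)
  obj <- function(loglam) {
    lam <- exp(loglam)
    ll <- subject_cond_loglik(s$dt, s$dz, lam, params$sigma_w, params$sigma_m)
    if (mode == "map" && params$tau_log_rate > 0) {
      ll <- ll + dlnorm(lam, params$mu_log_rate, params$tau_log_rate,
                        log = TRUE)
    }
    ll
  }
  opt <- optimize(obj, interval = c(-18, log(10)), maximum = TRUE,
                  tol = 1e-10)
  lam <- exp(opt$maximum)
  list(subject_id = s$subject_id, lambda_hat = lam,
       percent_per_year = 100 * (exp(lam) - 1))
}

#' Estimate subject-specific growth rates
#'
#' Given population parameters fitted on the full cohort, estimates each
#' subject's average growth rate by bounded 1-D optimisation over
#' \eqn{\log\lambda}. `mode = "map"` (default) maximises the subject
#' likelihood times the lognormal population prior density — the posterior
#' mode, which shrinks noisy series toward the population and keeps
#' shrinking subjects off the \eqn{\lambda \to 0} boundary. `mode =
#' "conditional_ml"` omits the prior (pure per-subject maximum likelihood on
#' the lognormal support \eqn{\lambda > 0}).
#'
#' @param cohort an `aaa_cohort`.
#' @param params a [growth_params()] or an `aaa_growth_fit` (its `params`
#'   and scale are used).
#' @param mode `"map"` or `"conditional_ml"`.
#' @return data frame with one row per subject with >= 2 usable visits:
#'   `subject_id`, `lambda_hat` (per year), `percent_per_year`
#'   `= 100 (e^{\lambda} - 1)`, `n_visits`, plus attribute `excluded` naming
#'   single-visit subjects (explicitly excluded, never silent `NaN`).
#' @export
individual_rates <- function(cohort, params, mode = c("map", "conditional_ml")) {
  mode <- match.arg(mode)
  if (inherits(params, "aaa_growth_fit")) params <- params$params
  stopifnot(inherits(params, "growth_params"))
  series <- if (inherits(cohort, "aaa_cohort")) {
    cohort_series(cohort, params$scale)
  } else {
    cohort
  }
  rows <- lapply(series, function(s) {
    r <- individual_rate_series(s, params, mode)
    data.frame(subject_id = r$subject_id, lambda_hat = r$lambda_hat,
               percent_per_year = r$percent_per_year,
               n_visits = length(s$dt) + 1L)
  })
  out <- if (length(rows) > 0L) {
    do.call(rbind, rows)
  } else {
    data.frame(subject_id = character(0), lambda_hat = numeric(0),
               percent_per_year = numeric(0), n_visits = integer(0))
  }
  rownames(out) <- NULL
  attr(out, "excluded") <- attr(series, "excluded")
  attr(out, "scale") <- attr(series, "scale") %||% params$scale
  attr(out, "mode") <- mode
  out
}

#' Growth rate of a single subject
#'
#' Convenience wrapper around [individual_rates()] for one subject.
#'
#' @param cohort an `aaa_cohort`.
#' @param subject_id subject label.
#' @inheritParams individual_rates
#' @return one-row data frame as in [individual_rates()]; errors if the
#'   subject has fewer than two usable visits.
#' @export
individual_rate <- function(cohort, subject_id, params,
                            mode = c("map", "conditional_ml")) {
  mode <- match.arg(mode)
  sub <- cohort[cohort$subject_id == subject_id, , drop = FALSE]
  if (nrow(sub) == 0L) stop("unknown subject: ", subject_id, call. = FALSE)
  out <- individual_rates(sub, params, mode)
  if (is.null(out) || nrow(out) == 0L) {
    stop(sprintf("subject %s has a single usable visit; excluded from rate estimation",
                 subject_id), call. = FALSE)
  }
  out
}
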