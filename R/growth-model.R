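# Hierarchical stochastic growth model: definition and marginal ML fitting.
#
# Conditional on a subject-specific average rate lambda, log-size follows
# Brownian motion with drift lambda - sigma_w^2/2 and volatility sigma_w, so
# that E[X(t)/X(0) | lambda] = exp(lambda * t) exactly. Observed log-sizes
# add independent N(0, sigma_m^2) measurement error. Across subjects lambda
# is lognormal: log(lambda) ~ N(mu_log_rate, tau_log_rate^2).

#' Population parameters of the stochastic growth model
#'
#' @param mu_log_rate mean of `log(lambda)` across subjects, where `lambda`
#'   is the subject-specific average exponential growth rate per year.
#' @param tau_log_rate SD of `log(lambda)` across subjects (>= 0).
#' @param sigma_w within-subject diffusion volatility of log-size, per
#'   square-root year (>= 0); captures phases of faster/slower growth within
#'   the same subject.
#' @param sigma_m SD of multiplicative (log-scale) measurement error (>= 0).
#' @param scale size scale the parameters refer to: `"diameter"`,
#'   `"volume"`, or `"cuberoot_volume"`.
#' @return object of class `growth_params`.
#' @export
growth_params <- function(mu_log_rate, tau_log_rate, sigma_w, sigma_m,
                          scale = "volume") {
  p <- c(mu_log_rate = mu_log_rate, tau_log_rate = tau_log_rate,
         sigma_w = sigma_w, sigma_m = sigma_m)
  if (!all(is.finite(p))) stop("growth parameters must be finite", call. = FALSE)
  if (tau_log_rate < 0 || sigma_w < 0 || sigma_m < 0) {
    stop("tau_log_rate, sigma_w and sigma_m must be >= 0", call. = FALSE)
  }
  scale <- match.arg(scale, SIZE_SCALES)
  structure(list(mu_log_rate = mu_log_rate, tau_log_rate = tau_log_rate,
                 sigma_w = sigma_w, sigma_m = sigma_m, scale = scale),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf("Growth-model parameters (%s scale):\n", x$scale))
  cat(sprintf("  mu_log_rate  %8.4f   (median rate %.2f %%/yr)\n",
              x$mu_log_rate, 100 * (exp(exp(x$mu_log_rate)) - 1)))
  cat(sprintf("  tau_log_rate %8.4f\n", x$tau_log_rate))
  cat(sprintf("  sigma_w      %8.4f   per sqrt(yr)\n", x$sigma_w))
  cat(sprintf("  sigma_m      %8.4f\n", x$sigma_m))
  invisible(x)
}

# Gauss-Hermite rule for E[f(Z)], Z ~ N(0,1):
# E[f(Z)] = sum(w/sqrt(pi) * f(sqrt(2) * x)).
gh_rule <- function(order) {
  if (order < 8) {
    stop("configuration error: Gauss-Hermite order must be >= 8", call. = FALSE)
  }
  key <- as.character(order)
  if (is.null(.gh_cache[[key]])) {
    .gh_cache[[key]] <- pracma::gaussHermite(order)
  }
  .gh_cache[[key]]
}
.gh_cache <- new.env(parent = emptyenv())

#' Marginal log-likelihood of the growth model
#'
#' Sum over subjects of the log marginal density of log-size increments from
#' each subject's first visit, integrating the subject rate over its
#' lognormal population distribution by Gauss-Hermite quadrature.
#' Single-visit subjects contribute 0.
#'
#' @param cohort an `aaa_cohort` (the size scale of `params` is applied), or
#'   a series list as produced internally.
#' @param params a [growth_params()] object.
#' @param gh_order quadrature order (>= 8).
#' @return total log-likelihood (scalar).
#' @export
growth_loglik <- function(cohort, params, gh_order = 64) {
  stopifnot(inherits(params, "growth_params"))
  series <- if (inherits(cohort, "aaa_cohort")) {
    cohort_series(cohort, params$scale)
  } else {
    cohort
  }
  for (s in series) {
    if (!all(is.finite(s$dt)) || !all(is.finite(s$dz))) {
      stop("non-finite values in cohort series", call. = FALSE)
    }
  }
  gh <- gh_rule(gh_order)
  growth_loglik_cpp(unname(series), params$mu_log_rate, params$tau_log_rate,
                    params$sigma_w, params$sigma_m, gh$x, gh$w)
}

# Crude starting values: population rate scale from per-subject overall
# log-slopes, diffusion scale from detrended consecutive increments.
growth_start <- function(series) {
  slopes <- vapply(series, function(s) {
    n <- length(s$dt)
    s$dz[n] / s$dt[n]
  }, numeric(1))
  pos <- slopes[slopes > 0]
  lambda0 <- if (length(pos) >= 3) median(pos) else 0.05
  tau0 <- if (length(pos) >= 3) min(max(sd(log(pos)), 0.2), 2) else 0.5
  r2g <- unlist(lapply(series, function(s) {
    if (length(s$dt) < 3L) return(NULL)
    g <- diff(c(0, s$dt))
    w <- diff(c(0, s$dz))
    n <- length(s$dt)
    (w - s$dz[n] / s$dt[n] * g)^2 / g
  }))
  sw0 <- if (length(r2g) >= 5) min(max(sqrt(median(r2g)), 0.01), 1) else 0.05
  growth_params(log(lambda0), tau0, sw0, 0.02)
}

# Internal fitting routine on a series list.
fit_growth_series <- function(series, scale, fix_sigma_m = NULL,
                              gh_order = 64, start = NULL, factr = 1e7) {
  if (length(series) < 2L) {
    stop("need >= 2 subjects with >= 2 visits to fit the growth model",
         call. = FALSE)
  }
  gh <- gh_rule(gh_order)
  su <- unname(series)
  lower <- c(mu = -12, ltau = log(1e-4), lsw = log(1e-4), lsm = log(1e-4))
  upper <- c(mu = 2, ltau = log(5), lsw = log(3), lsm = log(1))
  fixed_sm <- !is.null(fix_sigma_m)
  if (fixed_sm) stopifnot(fix_sigma_m >= 0)

  warm <- !is.null(start)
  if (!warm) start <- growth_start(series)
  par0 <- c(start$mu_log_rate,
            log(max(start$tau_log_rate, 1e-3)),
            log(max(start$sigma_w, 1e-3)))
  if (!fixed_sm) par0 <- c(par0, log(max(start$sigma_m, 1e-3)))
  par0 <- pmin(pmax(par0, lower[seq_along(par0)] + 1e-6),
               upper[seq_along(par0)] - 1e-6)

  np <- length(par0)
  lo <- lower[seq_len(np)]
  hi <- upper[seq_len(np)]
  negll <- function(theta) {
    if (any(theta < lo) || any(theta > hi)) return(1e10)
    sm <- if (fixed_sm) fix_sigma_m else exp(theta[4L])
    ll <- growth_loglik_cpp(su, theta[1L], exp(theta[2L]), exp(theta[3L]),
                            sm, gh$x, gh$w)
    if (!is.finite(ll)) 1e10 else -ll
  }
  # alternate simplex search (robust to poor starts; the surface has a
  # degenerate ridge) with a quasi-Newton polish, restarting until the
  # log-likelihood stops improving
  run_cycles <- function(par_init) {
    opt <- list(par = par_init, value = negll(par_init), convergence = 0L,
                message = NULL)
    for (cycle in seq_len(if (warm) 2L else 4L)) {
      nm <- optim(opt$par, negll, method = "Nelder-Mead",
                  control = list(maxit = if (warm) 300 else 2000,
                                 reltol = 1e-10))
      if (is.finite(nm$value) && nm$value < opt$value) opt <- nm
      lb <- tryCatch(
        optim(opt$par, negll, method = "L-BFGS-B", lower = lo, upper = hi,
              control = list(factr = factr, maxit = 500)),
        error = function(e) NULL)
      improved <- !is.null(lb) && is.finite(lb$value) &&
        lb$value < opt$value - 1e-8 * (1 + abs(opt$value))
      if (!is.null(lb) && is.finite(lb$value) && lb$value <= opt$value) {
        opt <- lb
      }
      if (!improved && cycle > 1L) break
    }
    opt
  }
  opt <- run_cycles(par0)
  if (!warm) {
    # second start at the degenerate corner: near-noiseless data create
    # spurious quadrature-induced optima that mask the tau, sigma -> 0 limit
    corner <- par0
    corner[2:np] <- lo[2:np] + 1e-6
    opt2 <- run_cycles(corner)
    if (is.finite(opt2$value) && opt2$value < opt$value) opt <- opt2
  }

  theta <- opt$par
  est <- growth_params(theta[1L], exp(theta[2L]), exp(theta[3L]),
                       if (fixed_sm) fix_sigma_m else exp(theta[4L]),
                       scale = scale)
  at_bound <- abs(theta - lower[seq_len(np)]) < 1e-3
  boundary <- c("tau_log_rate", "sigma_w", "sigma_m")[
    which(at_bound[-1L])]
  if (length(boundary) > 0L) {
    warning("parameter(s) at lower boundary (near-degenerate data): ",
            paste(boundary, collapse = ", "), call. = FALSE)
  }

  # Observed-information SEs on the natural scale via the delta method.
  se <- rep(NA_real_, 4L)
  names(se) <- c("mu_log_rate", "tau_log_rate", "sigma_w", "sigma_m")
  vc <- NULL
  if (!any(at_bound)) {
    H <- try(optimHess(theta, negll), silent = TRUE)
    if (!inherits(H, "try-error")) {
      Vt <- try(solve(H), silent = TRUE)
      if (!inherits(Vt, "try-error") && all(diag(Vt) > 0)) {
        J <- diag(c(1, exp(theta[2L]), exp(theta[3L]),
                    if (!fixed_sm) exp(theta[4L])), nrow = np)
        vc <- J %*% Vt %*% t(J)
        nm <- names(se)[seq_len(np)]
        dimnames(vc) <- list(nm, nm)
        se[seq_len(np)] <- sqrt(diag(vc))
      }
    }
  }
  if (fixed_sm) se["sigma_m"] <- NA_real_

  structure(list(params = est, se = se, vcov = vc,
                 logLik = -opt$value,
                 convergence = opt$convergence == 0L,
                 optim_message = opt$message,
                 boundary = boundary,
                 n_subjects = length(series),
                 excluded = attr(series, "excluded"),
                 gh_order = gh_order,
                 fixed_sigma_m = if (fixed_sm) fix_sigma_m else NULL,
                 series = series),
            class = "aaa_growth_fit")
}

#' Fit the stochastic growth model by marginal maximum likelihood
#'
#' Maximises [growth_loglik()] over `(mu_log_rate, tau_log_rate, sigma_w,
#' sigma_m)`, with the non-negative parameters optimised on the log scale
#' (boxed L-BFGS-B). Standard errors come from the observed information at
#' the optimum (delta method back to the natural scale); they are `NA` when
#' a parameter sits on its lower boundary. Deterministic given identical
#' inputs and options.
#'
#' @param cohort an `aaa_cohort`.
#' @param scale size scale to model; see [apply_scale()].
#' @param fix_sigma_m optional fixed value for the measurement-error SD
#'   (e.g. 0 when readings are treated as exact); default estimates it.
#' @param gh_order Gauss-Hermite quadrature order (default 64).
#' @param start optional [growth_params()] starting values.
#' @return object of class `aaa_growth_fit` with components `params`
#'   ([growth_params()]), `se`, `vcov`, `logLik`, `convergence`, `boundary`,
#'   `n_subjects`, `excluded` (single-visit subjects dropped).
#' @seealso [quantile.aaa_growth_fit()], [predict.aaa_growth_fit()],
#'   [individual_rates()], [loocv_calibration()]
#' @examples
#' sim <- simulate_cohort(simulation_config(n_subjects = 30, seed = 1))
#' fit <- fit_growth_model(sim$cohort, scale = "diameter", gh_order = 32)
#' coef(fit)
#' @export
fit_growth_model <- function(cohort, scale = c("volume", "diameter", "cuberoot_volume"),
                             fix_sigma_m = NULL, gh_order = 64, start = NULL) {
  scale <- match.arg(scale)
  series <- cohort_series(cohort, scale)
  fit <- fit_growth_series(series, scale = scale, fix_sigma_m = fix_sigma_m,
                           gh_order = gh_order, start = start)
  fit$call <- match.call()
  fit
}

#' @export
print.aaa_growth_fit <- function(x, ...) {
  cat("Stochastic growth model fit (", x$params$scale, " scale)\n", sep = "")
  cat(sprintf("  %d subjects (%d single-visit excluded); log-likelihood %.3f\n",
              x$n_subjects, length(x$excluded), x$logLik))
  if (!x$convergence) cat("  WARNING: optimizer did not report convergence\n")
  print(x$params)
  invisible(x)
}

#' @export
summary.aaa_growth_fit <- function(object, ...) {
  est <- unlist(object$params[c("mu_log_rate", "tau_log_rate", "sigma_w",
                                "sigma_m")])
  tab <- data.frame(estimate = est, se = object$se[names(est)])
  structure(list(table = tab, fit = object), class = "summary.aaa_growth_fit")
}

#' @export
print.summary.aaa_growth_fit <- function(x, ...) {
  print(x$fit)
  cat("\nEstimates and observed-information SEs:\n")
  print(round(x$table, 5))
  med <- 100 * (exp(exp(x$fit$params$mu_log_rate)) - 1)
  cat(sprintf("\nPopulation median growth rate: %.2f %%/yr\n", med))
  invisible(x)
}

#' @export
coef.aaa_growth_fit <- function(object, ...) {
  unlist(object$params[c("mu_log_rate", "tau_log_rate", "sigma_w", "sigma_m")])
}

#' @export
vcov.aaa_growth_fit <- function(object, ...) object$vcov

#' @export
logLik.aaa_growth_fit <- function(object, ...) {
  structure(object$logLik,
            df = 4L - as.integer(!is.null(object$fixed_sigma_m)),
            nobs = object$n_subjects, class = "logLik")
}

#' Quantiles of the population growth distribution from a fit
#'
#' @param x an `aaa_growth_fit`.
#' @param probs quantile levels in (0, 1).
#' @param horizon_years growth horizon t.
#' @param initial_value starting size for absolute growth, or `NULL` for
#'   relative growth in percent.
#' @param ... passed to [growth_distribution_quantile()].
#' @return named numeric vector of growth quantiles.
#' @export
quantile.aaa_growth_fit <- function(x, probs = c(0.05, 0.1, 0.25, 0.5, 0.75,
                                                 0.9, 0.95),
                                    horizon_years = 1, initial_value = NULL,
                                    ...) {
  growth_distribution_quantile(x$params, horizon_years = horizon_years,
                               level = probs, initial_value = initial_value,
                               ...)
}

#' Predictive quantiles of a future size from a fit
#'
#' @param object an `aaa_growth_fit`.
#' @param baseline_value observed size at baseline.
#' @param elapsed_years prediction horizon in years.
#' @param level quantile levels.
#' @param include_measurement_error whether the predicted quantity is an
#'   observed reading (adds measurement error; default) or the latent size.
#' @param ... unused.
#' @return named vector of predicted sizes.
#' @export
predict.aaa_growth_fit <- function(object, baseline_value, elapsed_years,
                                   level = c(0.05, 0.25, 0.5, 0.75, 0.95),
                                   include_measurement_error = TRUE, ...) {
  predictive_quantile(object$params, baseline_value, elapsed_years, level,
                      include_measurement_error = include_measurement_error)
}

#' Whitened residuals of the growth model
#'
#' Per subject, the log-size increments minus their conditional mean at the
#' subject's MAP rate, decorrelated by the Cholesky factor of the model
#' covariance. Approximately standard normal under a well-specified model.
#'
#' @param object an `aaa_growth_fit`.
#' @param ... unused.
#' @return data frame with `subject_id` and `residual`.
#' @export
residuals.aaa_growth_fit <- function(object, ...) {
  p <- object$params
  out <- lapply(object$series, function(s) {
    lam <- individual_rate_series(s, p, mode = "map")$lambda_hat
    S <- subject_covariance(s$dt, p$sigma_w, p$sigma_m)
    L <- t(chol(S))
    r <- forwardsolve(L, s$dz - (lam - p$sigma_w^2 / 2) * s$dt)
    data.frame(subject_id = s$subject_id, residual = r)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate observations from a fitted growth model
#'
#' Simulates new observed series on the same (subject, visit-time) design as
#' the data used for fitting, conditioning on each subject's observed
#' baseline value: a rate is drawn from the fitted lognormal population
#' distribution, the latent path by geometric Brownian motion, and
#' measurement error is added to the non-baseline readings.
#'
#' @param object an `aaa_growth_fit`.
#' @param nsim number of simulated replicates.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of `nsim` data frames (`subject_id`, `time_years`, `size`).
#' @export
simulate.aaa_growth_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$params
  one <- function() {
    rows <- lapply(object$series, function(s) {
      lam <- rlnorm(1, p$mu_log_rate, p$tau_log_rate)
      dt <- c(0, s$dt)
      gaps <- diff(dt)
      incr <- (lam - p$sigma_w^2 / 2) * gaps +
        p$sigma_w * sqrt(gaps) * rnorm(length(gaps))
      logx <- log(s$t0_value) + cumsum(c(0, incr))
      err <- c(0, rnorm(length(gaps), 0, p$sigma_m))
      data.frame(subject_id = s$subject_id, time_years = dt,
                 size = exp(logx + err))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
  replicate(nsim, one(), simplify = FALSE)
}

#' Plot observed relative growth with model quantile fan
#'
#' Observed per-subject relative size (value over baseline) against time,
#' overlaid with quantiles of the fitted latent relative-growth
#' distribution.
#'
#' @param x an `aaa_growth_fit`.
#' @param levels quantile levels for the reference curves.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.aaa_growth_fit <- function(x, levels = c(0.05, 0.25, 0.5, 0.75, 0.95),
                                ...) {
  tmax <- max(vapply(x$series, function(s) max(s$dt), numeric(1)))
  grid <- seq(0.02, tmax, length.out = 40)
  fan <- sapply(grid, function(t) {
    1 + growth_distribution_quantile(x$params, t, levels) / 100
  })
  matplot(grid, t(fan), type = "l", lty = 2, col = "black",
          xlab = "years since first visit", ylab = "relative size", ...)
  for (s in x$series) {
    lines(c(0, s$dt), exp(c(0, s$dz)), col = "grey60")
  }
  matlines(grid, t(fan), lty = c(2, 2, 1, 2, 2), col = "black")
  invisible(x)
}

# Covariance of log-size increments from the first visit.
subject_covariance <- function(dt, sigma_w, sigma_m) {
  n <- length(dt)
  sigma_w^2 * outer(dt, dt, pmin) + sigma_m^2 * (1 + diag(n))
}
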