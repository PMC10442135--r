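# Population growth distribution: the relative growth factor over t years is
# G = exp((lambda - sigma_w^2/2) * t + sigma_w * sqrt(t) * Z), lambda
# lognormal across subjects, Z standard normal. Optionally an extra
# multiplicative measurement error exp(sigma_m * Z') on the final reading.

# CDF of G at g (vectorised over g), by Gauss-Hermite quadrature over lambda.
growth_cdf <- function(g, params, horizon_years, include_measurement_error,
                       gh_order) {
  gh <- gh_rule(gh_order)
  lam <- exp(params$mu_log_rate + sqrt(2) * params$tau_log_rate * gh$x)
  w <- gh$w / sqrt(pi)
  drift <- (lam - params$sigma_w^2 / 2) * horizon_years
  sdt <- sqrt(params$sigma_w^2 * horizon_years +
                if (include_measurement_error) params$sigma_m^2 else 0)
  vapply(log(g), function(lg) {
    if (sdt > 0) {
      sum(w * pnorm((lg - drift) / sdt))
    } else {
      sum(w * (drift <= lg))
    }
  }, numeric(1))
}

# Quantile of G at level p (scalar p).
growth_factor_quantile <- function(p, params, horizon_years,
                                   include_measurement_error, gh_order) {
  sdt <- sqrt(params$sigma_w^2 * horizon_years +
                if (include_measurement_error) params$sigma_m^2 else 0)
  if (params$tau_log_rate == 0 && sdt == 0) {
    return(exp(exp(params$mu_log_rate) * horizon_years))
  }
  if (sdt == 0) {
    # degenerate diffusion: G = exp(lambda * t), lambda lognormal
    lam_p <- exp(params$mu_log_rate + params$tau_log_rate * qnorm(p))
    return(exp(lam_p * horizon_years))
  }
  gh <- gh_rule(gh_order)
  lam <- exp(params$mu_log_rate + sqrt(2) * params$tau_log_rate * gh$x)
  drift <- (lam - params$sigma_w^2 / 2) * horizon_years
  lo <- min(drift) - 10 * sdt
  hi <- max(drift) + 10 * sdt
  f <- function(lg) {
    growth_cdf(exp(lg), params, horizon_years, include_measurement_error,
               gh_order) - p
  }
  root <- uniroot(f, c(lo, hi), tol = 1e-12)$root
  exp(root)
}

#' Quantiles of the population growth distribution
#'
#' Quantiles of the relative growth factor \eqn{G} over a horizon of t
#' years, where \eqn{G = \exp((\lambda - \sigma_w^2/2)t + \sigma_w\sqrt{t}Z)}
#' with \eqn{\lambda} lognormal across subjects. By default measurement
#' error is excluded: the distribution describes latent true sizes (the
#' reference-curve use). The CDF is evaluated by Gauss-Hermite quadrature
#' over \eqn{\lambda} and inverted by bracketed root finding (tolerance well
#' below 1e-8 on G).
#'
#' @param params a [growth_params()] object.
#' @param horizon_years positive horizon t.
#' @param level quantile level(s) in (0, 1); vectorised.
#' @param initial_value starting size; if `NULL` (default) the result is the
#'   relative increase in percent, `100 * (G_p - 1)`; otherwise the absolute
#'   increase `initial_value * (G_p - 1)` in the size units.
#' @param include_measurement_error add the measurement-error factor
#'   (default `FALSE`).
#' @param gh_order Gauss-Hermite order.
#' @return named numeric vector of growth quantiles.
#' @examples
#' p <- growth_params(log(0.125), 0, 0, 0)
#' growth_distribution_quantile(p, 1, 0.5) # 100 * (exp(0.125) - 1)
#' @export
growth_distribution_quantile <- function(params, horizon_years, level,
                                         initial_value = NULL,
                                         include_measurement_error = FALSE,
                                         gh_order = 64) {
  stopifnot(inherits(params, "growth_params"), horizon_years > 0)
  if (any(level <= 0 | level >= 1)) {
    stop("quantile level must be strictly inside (0, 1)", call. = FALSE)
  }
  g <- vapply(level, growth_factor_quantile, numeric(1), params = params,
              horizon_years = horizon_years,
              include_measurement_error = include_measurement_error,
              gh_order = gh_order)
  out <- if (is.null(initial_value)) 100 * (g - 1) else initial_value * (g - 1)
  names(out) <- paste0("q", formatC(100 * level, format = "fg"))
  out
}

#' Mean of the population growth distribution
#'
#' `E[G] = E[exp(lambda * t)]` over the rate distribution (the diffusion
#' term cancels in expectation by construction). A lognormal rate
#' distribution is too heavy-tailed for this expectation to exist exactly,
#' so the mean is taken over the central part of the rate distribution,
#' excluding rates beyond `z_trunc` population SDs on the log scale (default
#' 5, i.e. all but ~6e-7 of subjects); it is computed by adaptive quadrature
#' and is insensitive to the cutoff for plausible `tau_log_rate`.
#'
#' @inheritParams growth_distribution_quantile
#' @param z_trunc rate-distribution truncation point in population log-SDs.
#' @return mean relative increase in percent, or absolute increase if
#'   `initial_value` is given.
#' @export
growth_distribution_mean <- function(params, horizon_years,
                                     initial_value = NULL,
                                     include_measurement_error = FALSE,
                                     gh_order = 64, z_trunc = 5) {
  stopifnot(inherits(params, "growth_params"), horizon_years > 0)
  mu <- params$mu_log_rate
  tau <- params$tau_log_rate
  if (tau == 0) {
    m <- exp(exp(mu) * horizon_years)
  } else {
    f <- function(z) dnorm(z) * exp(exp(mu + tau * z) * horizon_years)
    int <- tryCatch(
      stats::integrate(f, -z_trunc, z_trunc, rel.tol = 1e-10,
                       subdivisions = 500L),
      error = function(e) NULL)
    if (is.null(int) || !is.finite(int$value)) {
      stop(paste("growth mean is dominated by the extreme-rate tail",
                 "(tau_log_rate very large); reduce z_trunc or report",
                 "quantiles instead"), call. = FALSE)
    }
    m <- int$value / (1 - 2 * pnorm(-z_trunc))
  }
  if (include_measurement_error) m <- m * exp(params$sigma_m^2 / 2)
  if (is.null(initial_value)) 100 * (m - 1) else initial_value * (m - 1)
}

#' Predictive quantile of a future size
#'
#' Predicts the distribution of size after `elapsed_years` from an observed
#' baseline value: `baseline_value` times the quantile of the growth factor
#' G. By default the predicted quantity is a future *reading*, so the
#' measurement-error factor is included; the baseline is conditioned on as
#' observed (its error is ignored). Linear in `baseline_value`.
#'
#' @inheritParams growth_distribution_quantile
#' @param baseline_value observed size at baseline (positive).
#' @param elapsed_years positive prediction horizon.
#' @return predicted size(s) in the units of `baseline_value`.
#' @export
predictive_quantile <- function(params, baseline_value, elapsed_years, level,
                                include_measurement_error = TRUE,
                                gh_order = 64) {
  stopifnot(baseline_value > 0)
  g <- baseline_value +
    growth_distribution_quantile(params, elapsed_years, level,
                                 initial_value = baseline_value,
                                 include_measurement_error = include_measurement_error,
                                 gh_order = gh_order)
  g
}

#' Growth-distribution summary table
#'
#' Mean increase and quantiles of the 1-year (or other horizon) growth
#' distribution, as one relative row (percent, initial value 100%) and one
#' absolute row (size units) per requested starting value. Absolute rows are
#' exactly `initial_value / 100` times the relative row.
#'
#' @inheritParams growth_distribution_quantile
#' @param levels quantile levels in (0, 1).
#' @param initial_values starting sizes for the absolute rows.
#' @return data frame with columns `growth`, `initial_value`,
#'   `mean_increase` and one `q<level>` column per level.
#' @export
growth_quantile_table <- function(params, horizon_years = 1,
                                  levels = c(0.05, 0.1, 0.25, 0.5, 0.75, 0.9,
                                             0.95),
                                  initial_values = c(50, 100, 150),
                                  gh_order = 64) {
  rel <- growth_distribution_quantile(params, horizon_years, levels,
                                      gh_order = gh_order)
  rel_mean <- growth_distribution_mean(params, horizon_years,
                                       gh_order = gh_order)
  rows <- list(data.frame(growth = "relative_pct", initial_value = 100,
                          mean_increase = rel_mean,
                          as.list(rel), check.names = FALSE))
  for (v in initial_values) {
    rows[[length(rows) + 1L]] <-
      data.frame(growth = "absolute", initial_value = v,
                 mean_increase = v * rel_mean / 100,
                 as.list(v * rel / 100), check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
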