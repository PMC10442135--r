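# Predictive-quantile calibration by leave-one-out cross-validation, and
# resampling standard errors.

#' Binomial standard error under a perfect prediction model
#'
#' If predictive quantiles were exactly calibrated, the observed coverage at
#' nominal level q among n subjects would be binomial; its standard error in
#' percent is `100 * sqrt(q (1 - q) / n)`. Symmetric in q vs 1 - q and
#' maximal at q = 0.5.
#'
#' @param level nominal quantile level(s) in (0, 1).
#' @param n number of subjects entering the calibration.
#' @return SE in percentage points (vectorised over `level`).
#' @examples
#' perfect_model_se(0.25, 84) # 4.7
#' @export
perfect_model_se <- function(level, n) {
  if (any(level <= 0 | level >= 1)) {
    stop("level must be strictly inside (0, 1)", call. = FALSE)
  }
  stopifnot(n >= 1)
  100 * sqrt(level * (1 - level) / n)
}

#' Leave-one-out calibration of predictive quantiles
#'
#' For each subject with at least two usable visits, the growth model is
#' refitted on all other subjects and the distribution of the held-out
#' subject's final reading is predicted from their baseline value and
#' elapsed time. Observed coverage at each nominal level is the percentage
#' of subjects whose observed final value is less than or equal to the
#' predicted quantile (ties count as covered). Deterministic given data and
#' options.
#'
#' @param cohort an `aaa_cohort`.
#' @param scale size scale to model.
#' @param levels nominal quantile levels in (0, 1).
#' @param include_measurement_error include measurement error in the
#'   prediction (default: the comparison target is an observed reading).
#' @param fix_sigma_m,gh_order passed to the model fit.
#' @return data frame of class `calibration_table`: `level_pct`,
#'   `coverage_pct`, `se_pct` (perfect-model SE), `n`; attribute
#'   `failed_folds` counts folds whose refit failed (flagged and excluded).
#' @export
loocv_calibration <- function(cohort, scale = c("volume", "diameter",
                                                "cuberoot_volume"),
                              levels = c(0.05, 0.1, 0.25, 0.5, 0.75, 0.9,
                                         0.95),
                              include_measurement_error = TRUE,
                              fix_sigma_m = NULL, gh_order = 32) {
  scale <- match.arg(scale)
  series <- cohort_series(cohort, scale)
  if (length(series) < 3L) {
    stop("need >= 3 subjects with >= 2 visits for leave-one-out calibration",
         call. = FALSE)
  }
  full <- fit_growth_series(series, scale = scale, fix_sigma_m = fix_sigma_m,
                            gh_order = gh_order)
  ids <- names(series)
  covered <- matrix(NA, nrow = length(ids), ncol = length(levels))
  failed <- 0L
  for (i in seq_along(ids)) {
    s <- series[[i]]
    fit_i <- tryCatch(
      fit_growth_series(series[-i], scale = scale, fix_sigma_m = fix_sigma_m,
                        gh_order = gh_order, start = full$params),
      error = function(e) NULL)
    if (is.null(fit_i)) {
      failed <- failed + 1L
      next
    }
    nlast <- length(s$dt)
    q <- predictive_quantile(fit_i$params, s$t0_value, s$dt[nlast], levels,
                             include_measurement_error = include_measurement_error,
                             gh_order = gh_order)
    observed <- s$t0_value * exp(s$dz[nlast])
    covered[i, ] <- observed <= q
  }
  ok <- !is.na(covered[, 1L])
  n <- sum(ok)
  out <- data.frame(level_pct = 100 * levels,
                    coverage_pct = 100 * colMeans(covered[ok, , drop = FALSE]),
                    se_pct = perfect_model_se(levels, n),
                    n = n)
  attr(out, "failed_folds") <- failed
  attr(out, "scale") <- scale
  class(out) <- c("calibration_table", "data.frame")
  out
}

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf("Leave-one-out predictive-quantile calibration (%s scale, n = %d)\n",
              attr(x, "scale") %||% "?", x$n[1L]))
  print(data.frame(lapply(as.data.frame(x), round, 1)))
  ff <- attr(x, "failed_folds")
  if (!is.null(ff) && ff > 0L) cat(sprintf("%d fold(s) failed and were excluded\n", ff))
  invisible(x)
}

#' Nonparametric bootstrap standard errors over subjects
#'
#' Resamples subjects with replacement, recomputes a statistic on each
#' replicate cohort, and reports the SD of the replicate estimates. Seeded
#' and reproducible.
#'
#' @param cohort an `aaa_cohort`.
#' @param statistic function taking a cohort and returning a named numeric
#'   vector (see [growth_quantile_statistic()] and
#'   [size_relation_statistic()] for ready-made statistics).
#' @param B number of bootstrap replicates (>= 50).
#' @param seed integer seed.
#' @return named numeric vector of standard errors, with attributes `B` and
#'   `n_failed`; errors if more than 20% of replicate evaluations fail.
#' @export
bootstrap_se <- function(cohort, statistic, B = 200, seed = 1L) {
  stopifnot(inherits(cohort, "aaa_cohort"), is.function(statistic), B >= 50)
  set.seed(seed)
  ids <- unique(cohort$subject_id)
  sp <- split(seq_len(nrow(cohort)), cohort$subject_id)
  reps <- vector("list", B)
  n_failed <- 0L
  for (b in seq_len(B)) {
    take <- sample(ids, length(ids), replace = TRUE)
    rows <- lapply(seq_along(take), function(j) {
      block <- as.data.frame(cohort)[sp[[take[j]]], , drop = FALSE]
      block$subject_id <- sprintf("bs%04d", j)
      block
    })
    boot <- as_cohort(do.call(rbind, rows))
    val <- tryCatch(statistic(boot), error = function(e) NULL)
    if (is.null(val)) n_failed <- n_failed + 1L else reps[[b]] <- val
  }
  if (n_failed > 0.2 * B) {
    stop(sprintf("bootstrap failed: %d of %d replicate fits errored", n_failed, B),
         call. = FALSE)
  }
  mat <- do.call(rbind, reps[!vapply(reps, is.null, logical(1))])
  se <- apply(mat, 2L, sd)
  attr(se, "B") <- B
  attr(se, "n_failed") <- n_failed
  se
}

#' Ready-made bootstrap statistic: growth-distribution quantiles
#'
#' Returns a function suitable for [bootstrap_se()] that fits the growth
#' model on a cohort and evaluates relative growth quantiles and the mean
#' increase.
#'
#' @param scale size scale.
#' @param levels quantile levels in (0, 1).
#' @param horizon_years growth horizon.
#' @param fix_sigma_m,gh_order passed to [fit_growth_model()].
#' @return `function(cohort) -> named numeric`.
#' @export
growth_quantile_statistic <- function(scale = "volume",
                                      levels = c(0.05, 0.25, 0.5, 0.75, 0.95),
                                      horizon_years = 1, fix_sigma_m = NULL,
                                      gh_order = 32) {
  force(scale); force(levels); force(horizon_years)
  function(cohort) {
    fit <- fit_growth_model(cohort, scale = scale, fix_sigma_m = fix_sigma_m,
                            gh_order = gh_order)
    c(mean_increase = growth_distribution_mean(fit$params, horizon_years,
                                               gh_order = gh_order),
      growth_distribution_quantile(fit$params, horizon_years, levels,
                                   gh_order = gh_order))
  }
}

#' Ready-made bootstrap statistic: volume quantiles at given diameters
#'
#' @param diameters maximum diameters (mm).
#' @param levels quantile levels in (0, 1).
#' @return `function(cohort) -> named numeric` of volumes (ml).
#' @export
size_relation_statistic <- function(diameters = 55,
                                    levels = c(0.05, 0.5, 0.95)) {
  force(diameters); force(levels)
  function(cohort) {
    fit <- fit_size_relation(cohort)
    out <- c()
    for (d in diameters) {
      for (p in levels) {
        out[sprintf("d%g_q%g", d, 100 * p)] <-
          volume_quantile_at_diameter(fit, d, p)
      }
    }
    out
  }
}
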