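# Synthetic-cohort simulator: generates longitudinal diameter/volume data
# with the statistical structure the analysis assumes, plus a ground-truth
# table for recovery tests.

#' Configuration for the synthetic-cohort simulator
#'
#' Defaults emulate the monitored-cohort structure the analyses target: 84
#' subjects seen roughly every 6 months, 1-9 visits each (median 4, drawn
#' from a truncated geometric), baseline maximum diameter lognormal with
#' median 47 mm truncated to \[30, 68\] mm, cube-law coupling of baseline
#' volume to diameter via a subject-specific slope `N(slope_a, slope_sd^2)`
#' on the cube-root scale (`slope_a = 0.0926` ml^(1/3)/mm and
#' `slope_sd = 0.0108` back-solve the reported volume quantiles at 55 mm,
#' and give a baseline volume median near 81 ml), lognormal diameter growth
#' rates with median 3.8 %/yr, and a lognormal ratio (SD 0.45 on the log
#' scale) linking each subject's cube-root-volume rate to their diameter
#' rate so that all five rate-ratio classes are populated.
#'
#' @param n_subjects number of subjects.
#' @param visit_interval_years mean gap between visits (years).
#' @param visit_jitter_sd SD of the gap around the mean (years); gaps are
#'   floored at 0.1 years.
#' @param visits_per_subject `NULL` for the default truncated-geometric
#'   distribution on 1..9 (continuation probability 0.87, median 4), or a
#'   fixed integer.
#' @param baseline_diameter_median,baseline_diameter_sdlog,baseline_diameter_range
#'   lognormal baseline diameter (mm), truncated to the range by resampling.
#' @param slope_a,slope_sd mean and between-subject SD of the cube-law slope
#'   (ml^(1/3) per mm); non-positive draws are resampled with a warning.
#' @param mu_log_rate,tau_log_rate,sigma_w,sigma_m growth parameters on the
#'   diameter scale (see [growth_params()]). `sigma_w` and `sigma_m` are
#'   also used on the cube-root-volume scale.
#' @param log_ratio_sd SD of the log of the rate ratio between the
#'   cube-root-volume and diameter scales.
#' @param seed integer seed used by [simulate_cohort()].
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 84,
                              visit_interval_years = 0.5,
                              visit_jitter_sd = 0.06,
                              visits_per_subject = NULL,
                              baseline_diameter_median = 47,
                              baseline_diameter_sdlog = 0.17,
                              baseline_diameter_range = c(30, 68),
                              slope_a = 0.0926,
                              slope_sd = 0.0108,
                              mu_log_rate = log(0.038),
                              tau_log_rate = 0.6,
                              sigma_w = 0.05,
                              sigma_m = 0.01,
                              log_ratio_sd = 0.45,
                              seed = 1L) {
  cfg <- list(n_subjects = n_subjects,
              visit_interval_years = visit_interval_years,
              visit_jitter_sd = visit_jitter_sd,
              visits_per_subject = visits_per_subject,
              baseline_diameter_median = baseline_diameter_median,
              baseline_diameter_sdlog = baseline_diameter_sdlog,
              baseline_diameter_range = baseline_diameter_range,
              slope_a = slope_a, slope_sd = slope_sd,
              mu_log_rate = mu_log_rate, tau_log_rate = tau_log_rate,
              sigma_w = sigma_w, sigma_m = sigma_m,
              log_ratio_sd = log_ratio_sd, seed = seed)
  stopifnot(n_subjects >= 1, visit_interval_years > 0, visit_jitter_sd >= 0,
            tau_log_rate >= 0, sigma_w >= 0, sigma_m >= 0, log_ratio_sd >= 0,
            slope_a > 0, slope_sd >= 0, baseline_diameter_sdlog >= 0)
  if (!is.null(visits_per_subject)) {
    stopifnot(visits_per_subject >= 1)
  }
  class(cfg) <- "simulation_config"
  cfg
}

# Truncated geometric on 1..9, continuation probability q: median 4.
rvisits <- function(n, q = 0.87, kmax = 9L) {
  p <- q^(0:(kmax - 1L))
  sample.int(kmax, n, replace = TRUE, prob = p / sum(p))
}

#' Simulate a synthetic longitudinal AAA cohort
#'
#' Per subject: draw a diameter growth rate `lambda_d` from the lognormal
#' population distribution and a rate ratio `R` with `log R ~ N(0,
#' log_ratio_sd^2)`; set the cube-root-volume rate `lambda_v = lambda_d *
#' R`; draw a visit grid; simulate the latent diameter and cube-root-volume
#' paths as independent geometric Brownian motions (baseline cube-root
#' volume coupled to baseline diameter through a subject-specific cube-law
#' slope); apply multiplicative lognormal measurement error on each scale;
#' cube the cube-root series to obtain volume in ml. Morphology, sex and
#' smoking labels are drawn with cohort-like frequencies. Identical seeds
#' give identical output.
#'
#' @param config a [simulation_config()].
#' @return list with `cohort` (an `aaa_cohort`) and `truth` (per-subject
#'   data frame: `lambda_d`, `lambda_v`, percent rates, percent-rate
#'   `ratio`, `category`).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  ids <- sprintf("S%04d", seq_len(n))

  lambda_d <- rlnorm(n, config$mu_log_rate, config$tau_log_rate)
  ratio_r <- exp(rnorm(n, 0, config$log_ratio_sd))
  lambda_v <- lambda_d * ratio_r

  # truncated lognormal baseline diameter (resample out-of-range draws)
  rng <- config$baseline_diameter_range
  d0 <- rlnorm(n, log(config$baseline_diameter_median),
               config$baseline_diameter_sdlog)
  for (r in seq_len(100)) {
    bad <- d0 < rng[1L] | d0 > rng[2L]
    if (!any(bad)) break
    d0[bad] <- rlnorm(sum(bad), log(config$baseline_diameter_median),
                      config$baseline_diameter_sdlog)
  }
  d0 <- pmin(pmax(d0, rng[1L]), rng[2L])

  slope <- rnorm(n, config$slope_a, config$slope_sd)
  n_resampled <- 0L
  while (any(slope <= 0)) {
    bad <- slope <= 0
    n_resampled <- n_resampled + sum(bad)
    slope[bad] <- rnorm(sum(bad), config$slope_a, config$slope_sd)
  }
  if (n_resampled > 0L) {
    warning(n_resampled, " non-positive cube-law slope draw(s) resampled",
            call. = FALSE)
  }

  k <- if (is.null(config$visits_per_subject)) {
    rvisits(n)
  } else {
    rep.int(as.integer(config$visits_per_subject), n)
  }

  morph <- sample(MORPHOLOGY_LEVELS, n, replace = TRUE,
                  prob = c(63, 16, 1, 2, 2) / 84)
  sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.87, 0.13))
  smoking <- sample(c("current", "past_or_never"), n, replace = TRUE,
                    prob = c(0.36, 0.64))

  sw <- config$sigma_w; sm <- config$sigma_m
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    gaps <- if (k[i] > 1L) {
      pmax(config$visit_interval_years +
             rnorm(k[i] - 1L, 0, config$visit_jitter_sd), 0.1)
    } else {
      numeric(0)
    }
    tt <- cumsum(c(0, gaps))
    gbm <- function(x0, lam) {
      incr <- (lam - sw^2 / 2) * gaps + sw * sqrt(gaps) * rnorm(length(gaps))
      x0 * exp(cumsum(c(0, incr)))
    }
    d_lat <- gbm(d0[i], lambda_d[i])
    u_lat <- gbm(slope[i] * d0[i], lambda_v[i]) # cube-root volume, ml^(1/3)
    d_obs <- d_lat * exp(rnorm(k[i], 0, sm))
    u_obs <- u_lat * exp(rnorm(k[i], 0, sm))
    rows[[i]] <- data.frame(subject_id = ids[i], time_years = tt,
                            diameter_mm = d_obs, volume_ml = u_obs^3,
                            morphology = morph[i], sex = sex[i],
                            smoking = smoking[i])
  }
  cohort <- as_cohort(do.call(rbind, rows))

  pct_d <- 100 * (exp(lambda_d) - 1)
  pct_v3 <- 100 * (exp(lambda_v) - 1)
  ratio <- pct_v3 / pct_d
  truth <- data.frame(subject_id = ids, lambda_d = lambda_d,
                      lambda_v = lambda_v,
                      rate_diameter_pct = pct_d,
                      rate_cuberoot_volume_pct = pct_v3,
                      ratio = ratio, category = categorize_ratio(ratio),
                      n_visits = k, morphology = morph)
  list(cohort = cohort, truth = truth)
}

#' Analytic class probabilities of the simulated rate ratio
#'
#' Probabilities that the percent-per-year rate ratio between
#' cube-root-volume and diameter falls into each of the five
#' [categorize_ratio()] classes under the generator. Because the percent
#' ratio `(e^{lambda R} - 1)/(e^{lambda} - 1)` depends jointly on the rate
#' and the ratio, the probabilities are evaluated by high-n Monte Carlo
#' integration over the generator's joint distribution (method recorded in
#' the `method` attribute); the degenerate case `log_ratio_sd = 0` is exact.
#' The calling RNG state is preserved.
#'
#' @param config a [simulation_config()].
#' @param n_mc Monte Carlo sample size.
#' @return named probability vector over the five classes (sums to 1), with
#'   attribute `method`.
#' @export
truth_class_probabilities <- function(config = simulation_config(),
                                      n_mc = 1e6) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$log_ratio_sd == 0) {
    out <- setNames(c(0, 0, 1, 0, 0), RATE_CATEGORIES)
    attr(out, "method") <- "exact_degenerate"
    return(out)
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(20240101L)
  lam <- rlnorm(n_mc, config$mu_log_rate, config$tau_log_rate)
  r <- exp(rnorm(n_mc, 0, config$log_ratio_sd))
  ratio <- expm1(lam * r) / expm1(lam)
  tab <- table(categorize_ratio(ratio))
  out <- setNames(as.numeric(tab) / n_mc, names(tab))
  attr(out, "method") <- "monte_carlo"
  out
}
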