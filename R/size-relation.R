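# Cube-law relation between volume and maximum diameter:
# V_ij^{1/3} = (a + alpha_i) * d_ij + eps_ij, random slope alpha_i ~
# N(0, sigma_a^2), residual eps_ij ~ N(0, sigma_e^2), no intercept. The
# implied subject shape factor of V = s * d^3 is s_i = (a + alpha_i)^3.

# Marginal log-likelihood profile: given (sigma_a, sigma_e), subject i's
# cube-root volumes are MVN with mean a*d_i and covariance
# sigma_a^2 d_i d_i' + sigma_e^2 I — rank-one, so GLS and the log-density
# have closed forms via Sherman-Morrison.
size_relation_profile <- function(dd, yy, sa2, se2) {
  num <- 0; den <- 0
  for (i in seq_along(dd)) {
    d <- dd[[i]]; y <- yy[[i]]
    k <- sa2 / (se2 + sa2 * sum(d^2))
    # V^{-1} x = (x - k * d * (d'x)) / se2
    vd <- (d - k * d * sum(d * d)) / se2
    num <- num + sum(vd * y)
    den <- den + sum(vd * d)
  }
  a <- num / den
  ll <- 0
  for (i in seq_along(dd)) {
    d <- dd[[i]]; y <- yy[[i]]
    n <- length(d)
    r <- y - a * d
    k <- sa2 / (se2 + sa2 * sum(d^2))
    quad <- (sum(r^2) - k * sum(d * r)^2) / se2
    logdet <- (n - 1) * log(se2) + log(se2 + sa2 * sum(d^2))
    ll <- ll - 0.5 * (quad + logdet + n * log(2 * pi))
  }
  list(a = a, loglik = ll)
}

#' Fit the random-slope cube-law model of volume on diameter
#'
#' Maximum-likelihood fit of `V^(1/3) = (a + alpha_i) d + eps` with no
#' intercept, by direct marginal likelihood: the slope is profiled out in
#' closed form (GLS) and the two variance components are optimised on the
#' log scale. Deterministic.
#'
#' @param cohort an `aaa_cohort`; visits with both diameter and volume
#'   present are used.
#' @return object of class `size_relation_fit` with `a_hat` (mean slope,
#'   ml^(1/3) per mm), `sigma_a` (between-subject slope SD), `sigma_e`
#'   (residual SD on the cube-root scale), `logLik`, `n_subjects`, `n_obs`.
#' @examples
#' sim <- simulate_cohort(simulation_config(n_subjects = 40, seed = 2))
#' fit <- fit_size_relation(sim$cohort)
#' coef(fit)
#' @export
fit_size_relation <- function(cohort) {
  stopifnot(inherits(cohort, "aaa_cohort"))
  ok <- !is.na(cohort$diameter_mm) & !is.na(cohort$volume_ml)
  x <- cohort[ok, , drop = FALSE]
  if (length(unique(x$subject_id)) < 2L) {
    stop("need >= 2 subjects with paired diameter/volume visits", call. = FALSE)
  }
  sp <- split(seq_len(nrow(x)), x$subject_id)
  dd <- lapply(sp, function(i) x$diameter_mm[i])
  yy <- lapply(sp, function(i) x$volume_ml[i]^(1 / 3))
  if (max(vapply(dd, length, integer(1))) < 2L) {
    stop(paste("all subjects have a single paired visit: the between-subject",
               "slope SD is not identifiable; fit a pooled regression",
               "through the origin instead"), call. = FALSE)
  }
  # starting values from pooled regression through the origin
  dv <- unlist(dd); yv <- unlist(yy)
  a0 <- sum(dv * yv) / sum(dv^2)
  s0 <- sd(yv - a0 * dv)
  par0 <- log(c(max(0.2 * a0, 1e-4), max(s0, 1e-4)))
  neg <- function(theta) {
    -size_relation_profile(dd, yy, exp(2 * theta[1L]), exp(2 * theta[2L]))$loglik
  }
  opt <- optim(par0, neg, method = "L-BFGS-B",
               lower = log(c(1e-6, 1e-6)), upper = log(c(1, 10)),
               control = list(factr = 1e7))
  sa <- exp(opt$par[1L]); se <- exp(opt$par[2L])
  prof <- size_relation_profile(dd, yy, sa^2, se^2)
  structure(list(a_hat = prof$a, sigma_a = sa, sigma_e = se,
                 logLik = prof$loglik,
                 convergence = opt$convergence == 0L,
                 n_subjects = length(dd), n_obs = length(dv),
                 data = data.frame(subject_id = x$subject_id,
                                   diameter_mm = x$diameter_mm,
                                   cuberoot_volume = yv)),
            class = "size_relation_fit")
}

#' @export
print.size_relation_fit <- function(x, ...) {
  cat("Random-slope cube-law model: V^(1/3) = (a + alpha_i) * d + eps\n")
  cat(sprintf("  a_hat   %.5f ml^(1/3)/mm\n  sigma_a %.5f\n  sigma_e %.5f\n",
              x$a_hat, x$sigma_a, x$sigma_e))
  cat(sprintf("  %d subjects, %d paired visits; log-likelihood %.3f\n",
              x$n_subjects, x$n_obs, x$logLik))
  cat(sprintf("  median volume at 55 mm: %.1f ml\n",
              volume_quantile_at_diameter(x, 55, 0.5)))
  invisible(x)
}

#' @export
coef.size_relation_fit <- function(object, ...) {
  c(a_hat = object$a_hat, sigma_a = object$sigma_a, sigma_e = object$sigma_e)
}

#' @export
logLik.size_relation_fit <- function(object, ...) {
  structure(object$logLik, df = 3L, nobs = object$n_obs, class = "logLik")
}

#' @export
fitted.size_relation_fit <- function(object, ...) {
  object$a_hat * object$data$diameter_mm
}

#' @export
residuals.size_relation_fit <- function(object, ...) {
  object$data$cuberoot_volume - fitted(object)
}

#' Volume-distribution table at selected diameters
#'
#' @param object a `size_relation_fit`.
#' @param diameters maximum diameters (mm).
#' @param levels quantile levels in (0, 1).
#' @param ... unused.
#' @return data frame, one row per diameter, one column per level (volume,
#'   ml).
#' @export
predict.size_relation_fit <- function(object, diameters = c(30, 40, 50, 55, 60),
                                      levels = c(0.05, 0.25, 0.5, 0.75, 0.95),
                                      ...) {
  out <- data.frame(diameter_mm = diameters)
  for (p in levels) {
    out[[paste0("q", formatC(100 * p, format = "fg"))]] <-
      vapply(diameters, function(d) volume_quantile_at_diameter(object, d, p),
             numeric(1))
  }
  out
}

#' Quantile of volume at a given maximum diameter
#'
#' The population volume distribution at diameter d implied by the
#' random-slope model: `V_p = ((a + z_p * sigma_a) * d)^3` with `z_p` the
#' standard normal quantile. Only between-subject slope variability enters
#' (the residual SD describes visit-level scatter, not the between-subject
#' spread); set `include_residual = TRUE` for the full predictive spread
#' `((a + z sqrt(sigma_a^2 + sigma_e^2/d^2)) d)^3`.
#'
#' @param params a `size_relation_fit` or a list/vector with `a_hat` and
#'   `sigma_a` (and `sigma_e` if `include_residual`).
#' @param d_mm maximum diameter in mm (vectorised).
#' @param level quantile level in (0, 1) (scalar).
#' @param include_residual add residual variance to the slope spread
#'   (default `FALSE`, the reference formula).
#' @return volume in ml; scales exactly as d^3.
#' @export
volume_quantile_at_diameter <- function(params, d_mm, level,
                                        include_residual = FALSE) {
  stopifnot(all(d_mm > 0), level > 0, level < 1)
  p <- as.list(params)
  sa <- p$sigma_a
  if (include_residual) sa <- sqrt(p$sigma_a^2 + p$sigma_e^2 / d_mm^2)
  slope <- p$a_hat + qnorm(level) * sa
  if (any(slope <= 0)) {
    stop("requested level implies a non-positive slope quantile (volume would be non-positive)",
         call. = FALSE)
  }
  (slope * d_mm)^3
}

#' Diameter-to-height ratio of an ellipsoidal aneurysm
#'
#' For an idealised ellipsoid with circular cross sections, maximum diameter
#' d and height h, the volume is `V = pi/6 * d^2 * h`, so
#' `d/h = d^3 / V * pi/6` with V in mm^3. Volume is supplied in ml and
#' converted internally (1 ml = 1000 mm^3). Equals 1 exactly for a sphere.
#'
#' @param d_mm maximum diameter (mm, positive).
#' @param V_ml volume (ml, positive).
#' @return dimensionless d/h ratio (vectorised).
#' @examples
#' ellipsoid_ratio(55, 132) # 0.66
#' @export
ellipsoid_ratio <- function(d_mm, V_ml) {
  if (any(d_mm <= 0) || any(V_ml <= 0)) {
    stop("d_mm and V_ml must be positive", call. = FALSE)
  }
  d_mm^3 / (1000 * V_ml) * pi / 6
}

#' Repeated-measures (within-subject) correlation
#'
#' The Bland-Altman correlation for repeated measurements: paired
#' observations are centred within subject and pooled,
#' \deqn{r = \frac{\sum_i \sum_j (x_{ij} - \bar x_i)(y_{ij} - \bar y_i)}{
#'   \sqrt{\sum (x_{ij} - \bar x_i)^2 \sum (y_{ij} - \bar y_i)^2}}.}
#' Equals the signed square root of the extra
#' variation in y explained by x after adjusting for subject as a fixed
#' effect. Invariant to per-subject additive shifts.
#'
#' @param x,y numeric vectors of paired measurements.
#' @param subject grouping vector of the same length.
#' @return correlation in \[-1, 1\].
#' @export
repeated_measures_correlation <- function(x, y, subject) {
  stopifnot(length(x) == length(y), length(x) == length(subject))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]; subject <- subject[ok]
  counts <- table(subject)
  if (!any(counts >= 2L)) {
    stop("repeated-measures correlation undefined: no subject with >= 2 paired visits",
         call. = FALSE)
  }
  xc <- x - ave(x, subject)
  yc <- y - ave(y, subject)
  den <- sqrt(sum(xc^2) * sum(yc^2))
  if (den == 0) {
    stop("repeated-measures correlation undefined: no within-subject variation",
         call. = FALSE)
  }
  sum(xc * yc) / den
}

#' Pearson correlation at baseline
#'
#' Plain Pearson correlation of two measurements across subjects' first
#' visits (use [first_visits()] to extract them from a cohort).
#'
#' @param x,y numeric vectors (one value per subject, >= 3 subjects).
#' @return correlation in \[-1, 1\].
#' @export
baseline_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 subjects", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("baseline correlation undefined: zero variance", call. = FALSE)
  }
  stats::cor(x, y)
}
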