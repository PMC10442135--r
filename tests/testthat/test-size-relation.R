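make_cube_law_cohort <- function(n_subjects, visits = 4, a = 0.0926,
                                 sigma_a = 0.0108, sigma_e = 0.05,
                                 seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n_subjects), function(i) {
    d0 <- runif(1, 32, 65)
    tt <- (seq_len(visits) - 1) * 0.5
    d <- d0 * exp(0.03 * tt)
    u <- (a + rnorm(1, 0, sigma_a)) * d + rnorm(visits, 0, sigma_e)
    data.frame(subject_id = sprintf("C%03d", i), time_years = tt,
               diameter_mm = d, volume_ml = pmax(u, 0.5)^3)
  })
  as_cohort(do.call(rbind, rows))
}

test_that("a deterministic cube law is recovered exactly", {
  co <- make_exponential_cohort(n_subjects = 8, lambda = 0.04, slope = 0.09)
  fit <- fit_size_relation(co)
  expect_equal(fit$a_hat, 0.09, tolerance = 1e-5)
  expect_lt(fit$sigma_a, 1e-3)
  expect_lt(fit$sigma_e, 1e-3)
  expect_equal(unname(volume_quantile_at_diameter(fit, 50, 0.5)),
               (0.09 * 50)^3, tolerance = 1e-4)
})

test_that("generating parameters are recovered on a simulated cohort", {
  co <- make_cube_law_cohort(200, seed = 5)
  fit <- fit_size_relation(co)
  expect_equal(fit$a_hat, 0.0926, tolerance = 0.02)
  expect_equal(fit$sigma_a, 0.0108, tolerance = 0.25)
  expect_equal(fit$sigma_e, 0.05, tolerance = 0.15)
})

test_that("direct marginal fit matches a brute-force optimiser and lme4", {
  co <- make_cube_law_cohort(5, visits = 3, seed = 9)
  fit <- fit_size_relation(co)

  # brute force: full MVN marginal likelihood, simplex search from several
  # starting points, all independent of the package's profile formulation
  dd <- split(co$diameter_mm, co$subject_id)
  yy <- split(co$volume_ml^(1 / 3), co$subject_id)
  negll <- function(theta) {
    a <- theta[1L]; sa2 <- exp(2 * theta[2L]); se2 <- exp(2 * theta[3L])
    -sum(mapply(function(d, y) {
      ref_mvn_logdens(y, a * d, sa2 * outer(d, d) + se2 * diag(length(d)))
    }, dd, yy))
  }
  best <- NULL
  for (s0 in list(c(0.09, log(0.01), log(0.05)),
                  c(0.1, log(0.05), log(0.1)),
                  c(0.08, log(0.002), log(0.02)))) {
    o <- optim(s0, negll, control = list(maxit = 5000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  expect_equal(fit$a_hat, best$par[1L], tolerance = 1e-3)
  expect_equal(fit$logLik, -best$value, tolerance = 1e-4)

  # independent mixed-model implementation on a larger instance
  co2 <- make_cube_law_cohort(80, seed = 11)
  fit2 <- fit_size_relation(co2)
  df <- data.frame(y = co2$volume_ml^(1 / 3), d = co2$diameter_mm,
                   id = co2$subject_id)
  lmm <- lme4::lmer(y ~ 0 + d + (0 + d | id), data = df, REML = FALSE)
  expect_equal(fit2$a_hat, unname(lme4::fixef(lmm)), tolerance = 1e-3)
  expect_equal(fit2$sigma_a,
               attr(lme4::VarCorr(lmm)$id, "stddev")[["d"]], tolerance = 0.02)
  expect_equal(fit2$sigma_e, stats::sigma(lmm), tolerance = 0.02)
})

test_that("slope-SD is unidentifiable from single-visit subjects", {
  co <- as_cohort(data.frame(subject_id = c("A", "B", "C"),
                             time_years = 0,
                             diameter_mm = c(40, 50, 60),
                             volume_ml = c(48, 95, 160)))
  expect_error(fit_size_relation(co), "not identifiable")
})

test_that("volume quantiles scale exactly as diameter cubed and grow in level", {
  prm <- list(a_hat = 0.0926, sigma_a = 0.0108)
  for (lv in c(0.05, 0.5, 0.95)) {
    q30 <- volume_quantile_at_diameter(prm, 30, lv)
    q55 <- volume_quantile_at_diameter(prm, 55, lv)
    expect_equal(q30 / q55, (30 / 55)^3, tolerance = 1e-12)
  }
  lv <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  q <- vapply(lv, function(p) volume_quantile_at_diameter(prm, 55, p),
              numeric(1))
  expect_true(all(diff(q) > 0))
  # sigma_a = 0: every level returns (a d)^3
  expect_equal(volume_quantile_at_diameter(list(a_hat = 0.09, sigma_a = 0),
                                           40, 0.95), (0.09 * 40)^3)
  # level so extreme the slope quantile is negative
  expect_error(volume_quantile_at_diameter(prm, 55, 1e-30), "non-positive")
})

test_that("ellipsoid ratio identities", {
  # a sphere has d/h = 1 exactly
  expect_equal(ellipsoid_ratio(40, pi * 40^3 / 6 / 1000), 1, tolerance = 1e-12)
  # ratio * V is proportional to d^3 with constant pi/6000
  d <- c(30, 45, 60); V <- c(20, 90, 180)
  expect_equal(ellipsoid_ratio(d, V) * V, pi / 6000 * d^3, tolerance = 1e-12)
  expect_error(ellipsoid_ratio(-5, 10), "positive")
  expect_error(ellipsoid_ratio(50, 0), "positive")
})

test_that("repeated-measures correlation: exact cases and ANCOVA oracle", {
  # perfectly linear within subject (different intercepts)
  x <- c(1, 2, 3, 4, 10, 11, 12)
  y <- c(5, 7, 9, 11, 2, 4, 6)
  g <- c("a", "a", "a", "a", "b", "b", "b")
  expect_equal(repeated_measures_correlation(x, y, g), 1)
  expect_equal(repeated_measures_correlation(x, -y, g), -1)

  # constructed zero case: within-subject cross-products cancel
  x0 <- c(-1, 0, 1, -1, 0, 1)
  y0 <- c(1, -2, 1, 1, -2, 1)
  g0 <- rep(c("a", "b"), each = 3)
  expect_equal(repeated_measures_correlation(x0, y0, g0), 0)

  # invariant to per-subject additive shifts
  set.seed(13)
  xr <- rnorm(20); yr <- xr * 0.5 + rnorm(20, 0, 0.3)
  gr <- rep(letters[1:5], each = 4)
  shift <- rep(rnorm(5, 0, 10), each = 4)
  expect_equal(repeated_measures_correlation(xr, yr, gr),
               repeated_measures_correlation(xr + shift, yr - 2 * shift, gr),
               tolerance = 1e-12)

  # signed square root of the R^2 gain over a subject-only regression
  rss1 <- sum(resid(lm(yr ~ factor(gr)))^2)
  rss2 <- sum(resid(lm(yr ~ factor(gr) + xr))^2)
  expect_equal(repeated_measures_correlation(xr, yr, gr),
               sqrt(1 - rss2 / rss1), tolerance = 1e-10)

  expect_error(repeated_measures_correlation(1:3, 1:3, c("a", "b", "c")),
               ">= 2 paired visits")
})

test_that("baseline Pearson correlation matches the textbook formula", {
  expect_equal(baseline_pearson(1:5, 1:5), 1)
  expect_equal(baseline_pearson(1:5, 5:1), -1)
  x <- c(1, 3, 4, 7, 9); y <- c(2, 3, 7, 6, 10)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(baseline_pearson(x, y), r_hand, tolerance = 1e-12)
  expect_error(baseline_pearson(c(1, 1, 1), 1:3), "zero variance")
  expect_error(baseline_pearson(1:2, 1:2), ">= 3 subjects")
})
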