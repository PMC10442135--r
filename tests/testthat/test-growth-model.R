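test_that("marginal likelihood matches adaptive-quadrature oracle", {
  # one subject, two visits, no measurement error: 1-D integral over lambda
  s2 <- list(A = list(subject_id = "A", dt = 0.8, dz = 0.07, t0_value = 50))
  p <- growth_params(log(0.1), 0.5, 0.08, 0)
  expect_equal(growth_loglik(s2, p, gh_order = 64),
               ref_subject_marginal(0.8, 0.07, log(0.1), 0.5, 0.08, 0),
               tolerance = 1e-6)
  # three visits with measurement error
  s3 <- list(A = list(subject_id = "A", dt = c(0.5, 1.1), dz = c(0.05, 0.12),
                      t0_value = 50))
  p2 <- growth_params(log(0.08), 0.7, 0.05, 0.02)
  expect_equal(growth_loglik(s3, p2, gh_order = 64),
               ref_subject_marginal(c(0.5, 1.1), c(0.05, 0.12),
                                    log(0.08), 0.7, 0.05, 0.02),
               tolerance = 1e-6)
})

test_that("degenerate rate distribution reduces to a fixed-rate normal density", {
  dt <- c(0.5, 1, 1.6)
  dz <- c(0.04, 0.11, 0.18)
  s <- list(A = list(subject_id = "A", dt = dt, dz = dz, t0_value = 80))
  lam <- exp(-2.2)
  p <- growth_params(-2.2, 0, 0.06, 0.015)
  S <- 0.06^2 * outer(dt, dt, pmin) + 0.015^2 * (1 + diag(3))
  expect_equal(growth_loglik(s, p),
               ref_mvn_logdens(dz, (lam - 0.06^2 / 2) * dt, S),
               tolerance = 1e-10)
})

test_that("single-visit subjects contribute zero log-likelihood", {
  s <- list(A = list(subject_id = "A", dt = numeric(0), dz = numeric(0),
                     t0_value = 50))
  p <- growth_params(log(0.1), 0.5, 0.1, 0.01)
  expect_identical(growth_loglik(s, p), 0)
})

test_that("likelihood configuration and input validation", {
  s <- list(A = list(subject_id = "A", dt = 1, dz = 0.1, t0_value = 50))
  p <- growth_params(log(0.1), 0.5, 0.1, 0.01)
  expect_error(growth_loglik(s, p, gh_order = 4), "order must be >= 8")
  s_bad <- list(A = list(subject_id = "A", dt = 1, dz = NaN, t0_value = 50))
  expect_error(growth_loglik(s_bad, p), "non-finite")
  expect_error(growth_params(log(0.1), -0.1, 0.1, 0.01), ">= 0")
})

test_that("likelihood is invariant to rescaling all sizes", {
  sim <- simulate_cohort(simulation_config(n_subjects = 15, seed = 4))
  co <- sim$cohort
  co2 <- co
  co2$diameter_mm <- co2$diameter_mm * 3.7
  p <- growth_params(log(0.05), 0.5, 0.05, 0.01, scale = "diameter")
  expect_equal(growth_loglik(co, p), growth_loglik(co2, p),
               tolerance = 1e-10)
})

test_that("noiseless exponential growth drives the fit to the degenerate corner", {
  co <- make_exponential_cohort(n_subjects = 12, lambda = 0.1, n_visits = 4)
  fit <- suppressWarnings(
    fit_growth_model(co, scale = "diameter", fix_sigma_m = 0, gh_order = 16))
  expect_equal(fit$params$mu_log_rate, log(0.1), tolerance = 1e-3)
  expect_lt(fit$params$tau_log_rate, 0.01)
  expect_lt(fit$params$sigma_w, 0.01)
  expect_true(length(fit$boundary) > 0L)  # boundary warning was raised
})

test_that("the fitted optimum dominates the generating parameters", {
  cfg <- simulation_config(n_subjects = 60, seed = 21)
  sim <- simulate_cohort(cfg)
  fit <- fit_growth_model(sim$cohort, scale = "diameter", gh_order = 32)
  truth <- growth_params(cfg$mu_log_rate, cfg$tau_log_rate, cfg$sigma_w,
                         cfg$sigma_m, scale = "diameter")
  expect_true(fit$convergence)
  expect_gte(fit$logLik, growth_loglik(sim$cohort, truth, 32))
  # deterministic: same data, same options, same fit
  fit2 <- fit_growth_model(sim$cohort, scale = "diameter", gh_order = 32)
  expect_identical(coef(fit), coef(fit2))
})

test_that("cube-root rescaling of volume data maps the parameters by the cube law", {
  # deterministic: exact exponential volume growth at rate 3*lambda gives
  # cube-root rate lambda
  co <- make_exponential_cohort(n_subjects = 12, lambda = 0.05, n_visits = 4)
  fit <- suppressWarnings(
    fit_growth_model(co, scale = "cuberoot_volume", fix_sigma_m = 0,
                     gh_order = 16))
  expect_equal(fit$params$mu_log_rate, log(0.05), tolerance = 1e-3)

  # stochastic: volume-scale diffusion sigma_w appears as sigma_w / 3 on the
  # cube-root scale (and the drift mapping lambda_c = lambda_v/3 - sw^2/9
  # follows from dividing the log-scale drift by 3)
  set.seed(99)
  sw <- 0.09
  rows <- lapply(1:250, function(i) {
    lam_v <- rlnorm(1, log(0.12), 0.5)
    tt <- seq(0, 2.5, by = 0.5)
    gaps <- diff(tt)
    incr <- (lam_v - sw^2 / 2) * gaps + sw * sqrt(gaps) * rnorm(5)
    data.frame(subject_id = sprintf("V%03d", i), time_years = tt,
               diameter_mm = NA_real_,
               volume_ml = 80 * exp(cumsum(c(0, incr))))
  })
  co2 <- as_cohort(do.call(rbind, rows))
  fitc <- fit_growth_model(co2, scale = "cuberoot_volume", fix_sigma_m = 0,
                           gh_order = 32)
  expect_equal(fitc$params$sigma_w, sw / 3, tolerance = 0.15)
  lam_c_med <- exp(fitc$params$mu_log_rate)
  expect_equal(lam_c_med, 0.12 / 3 - sw^2 / 9, tolerance = 0.15)
})

test_that("fit requires at least two informative subjects", {
  co <- as_cohort(data.frame(subject_id = c("A", "A", "B"),
                             time_years = c(0, 1, 0),
                             diameter_mm = c(40, 42, 50),
                             volume_ml = c(60, 66, 80)))
  expect_error(fit_growth_model(co, scale = "diameter"), ">= 2 subjects")
})
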