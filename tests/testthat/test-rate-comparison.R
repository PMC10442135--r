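test_that("rate-ratio categories follow the documented bands and boundaries", {
  expect_equal(as.character(categorize_ratio(1.0)), "equivalent")
  expect_equal(as.character(categorize_ratio(1.5)), "moderately_faster_volume")
  expect_equal(as.character(categorize_ratio(2.5)),
               "considerably_faster_volume")
  expect_equal(as.character(categorize_ratio(0.6)),
               "moderately_faster_diameter")
  expect_equal(as.character(categorize_ratio(0.4)),
               "considerably_faster_diameter")
  # closed equivalence band; outer bounds closed toward the moderate class
  expect_equal(as.character(categorize_ratio(c(0.8, 1.25))),
               rep("equivalent", 2))
  expect_equal(as.character(categorize_ratio(c(0.5, 2))),
               c("moderately_faster_diameter", "moderately_faster_volume"))
  expect_error(categorize_ratio(-1), "positive")
  expect_error(categorize_ratio(Inf), "positive")
})

test_that("reciprocal ratios map to mirror classes outside the equivalence band", {
  for (r in c(0.3, 0.6, 1.6, 3)) {
    a <- as.integer(categorize_ratio(r))
    b <- as.integer(categorize_ratio(1 / r))
    expect_equal(a + b, 6L)  # classes are 1..5, mirrored around 3
  }
})

test_that("identical growth on both scales gives 100% equivalent", {
  co <- make_exponential_cohort(n_subjects = 10, lambda = 0.04, n_visits = 3)
  pd <- growth_params(log(0.04), 0.3, 1e-3, 0, scale = "diameter")
  pv <- growth_params(log(0.04), 0.3, 1e-3, 0, scale = "cuberoot_volume")
  cmp <- compare_rates(co, pd, pv)
  expect_equal(unname(cmp$proportions["equivalent"]), 1)
  expect_equal(sum(cmp$proportions), 1)
  expect_true(all(abs(cmp$records$ratio - 1) < 0.01))
  # volume percent rate is the cube-law transform of the cube-root rate
  expect_equal(cmp$records$rate_volume_pct,
               100 * ((1 + cmp$records$rate_cuberoot_volume_pct / 100)^3 - 1))
})

test_that("class proportions form a partition on a heterogeneous cohort", {
  cfg <- simulation_config(n_subjects = 150, sigma_w = 0, sigma_m = 0,
                           seed = 17)
  sim <- simulate_cohort(cfg)
  pd <- growth_params(cfg$mu_log_rate, cfg$tau_log_rate, 1e-3, 0,
                      scale = "diameter")
  pv <- growth_params(cfg$mu_log_rate,
                      sqrt(cfg$tau_log_rate^2 + cfg$log_ratio_sd^2), 1e-3, 0,
                      scale = "cuberoot_volume")
  cmp <- compare_rates(sim$cohort, pd, pv)
  expect_equal(sum(cmp$proportions), 1, tolerance = 1e-12)
  expect_equal(nrow(cmp$records),
               sum(table(sim$cohort$subject_id) >= 2))
  # noiseless data: estimated categories agree with the generator's truth
  truth <- sim$truth[match(cmp$records$subject_id, sim$truth$subject_id), ]
  agree <- mean(as.character(cmp$records$category) ==
                  as.character(truth$category))
  expect_gt(agree, 0.95)
})

test_that("changes from baseline: identities and the cube law", {
  co <- as_cohort(data.frame(subject_id = c("A", "A", "A"),
                             time_years = c(0, 0.5, 1),
                             diameter_mm = c(40, 41, 43),
                             volume_ml = c(100, 110, 120)))
  ch <- changes_from_baseline(co, "volume")
  expect_equal(ch$absolute_change, c(0, 10, 20))
  expect_equal(ch$relative_change, c(1, 1.1, 1.2))
  ch3 <- changes_from_baseline(co, "cuberoot_volume")
  expect_equal(ch3$relative_change^3, ch$relative_change, tolerance = 1e-12)
  expect_equal(ch3$absolute_change[1], 0)
})

test_that("group summaries report median (min-max) per morphology", {
  rec <- data.frame(subject_id = as.character(1:6),
                    rate_diameter_pct = c(6.8, 1, 2, 3, 4, 5),
                    rate_cuberoot_volume_pct = c(10.9, 1.2, 2.1, 3.3, 4.0, 5.5),
                    rate_volume_pct = c(36.6, 4, 6, 10, 12, 17),
                    ratio = c(1.61, 1.2, 1.05, 1.1, 1.0, 1.1),
                    morphology = c("eccentric", rep("fusiform", 5)))
  s <- summarize_rates_by_group(rec, "morphology")
  ecc <- s[s$morphology == "eccentric", ]
  expect_equal(ecc$n, 1L)
  expect_equal(ecc$rate_diameter_pct_median, 6.8)
  expect_equal(ecc$rate_diameter_pct_min, 6.8)
  expect_equal(ecc$rate_diameter_pct_max, 6.8)
  expect_equal(ecc$rate_diameter_pct_label, "6.8 (6.8-6.8)")
  fus <- s[s$morphology == "fusiform", ]
  expect_equal(fus$rate_diameter_pct_median, 3)
  expect_equal(c(fus$rate_diameter_pct_min, fus$rate_diameter_pct_max),
               c(1, 5))
  expect_error(summarize_rates_by_group(rec, "nonexistent"), "unknown")
})

test_that("group summaries agree with an order-statistics oracle", {
  set.seed(23)
  rec <- data.frame(subject_id = as.character(1:40),
                    rate_diameter_pct = rnorm(40, 4, 2),
                    rate_cuberoot_volume_pct = rnorm(40, 4, 2),
                    rate_volume_pct = rnorm(40, 13, 5),
                    ratio = exp(rnorm(40, 0, 0.4)),
                    morphology = sample(c("fusiform", "saccular"), 40, TRUE))
  s <- summarize_rates_by_group(rec, "morphology")
  for (grp in s$morphology) {
    v <- sort(rec$ratio[rec$morphology == grp])
    n <- length(v)
    med <- if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
    expect_equal(s$ratio_median[s$morphology == grp], med)
    expect_equal(s$ratio_min[s$morphology == grp], v[1])
    expect_equal(s$ratio_max[s$morphology == grp], v[n])
  }
})
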