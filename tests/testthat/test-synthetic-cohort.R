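test_that("configuration is validated", {
  expect_error(generator_config(event_rate_target = 0), "strictly between")
  expect_error(generator_config(event_rate_target = 1), "strictly between")
  expect_error(generator_config(effect_vector = c(a = Inf)), "finite")
  expect_error(generator_config(effect_vector = c(1, 2)), "named")
  expect_error(generator_config(missingness_rate = 1), "\\[0, 1\\)")
  spec <- default_dose_metric_spec()
  expect_error(generator_config(dose_metric_spec = rbind(spec, spec[1, ])),
               "duplicate")
  spec_bad <- spec; spec_bad$dose_gy[1] <- -1
  expect_error(generator_config(dose_metric_spec = spec_bad), "positive")
  expect_error(generate_cohort(
    generator_config(effect_vector = c(not_a_feature = 1))), "unknown")
})

test_that("same seed reproduces the cohort byte for byte", {
  a <- generate_cohort(generator_config(n_patients = 120, seed = 42))
  b <- generate_cohort(generator_config(n_patients = 120, seed = 42))
  expect_identical(a$data, b$data)
  expect_identical(a$dvh, b$dvh)
  expect_identical(a$truth$intercept, b$truth$intercept)
})

test_that("event-rate calibration hits its target", {
  # intercept-only model: no effects, target 0.5
  co0 <- generate_cohort(generator_config(
    n_patients = 589, seed = 5, event_rate_target = 0.5,
    effect_vector = c(age = 0)))
  expect_lt(abs(co0$truth$event_rate - 0.5), 0.06)

  # the study conditions: n = 589 at 57.7% events; the realised rate carries
  # binomial noise (sd ~2pp), so the +/-3pp band is asserted on the mean over
  # replicates and loosely per replicate
  rates <- vapply(1:10, function(s) {
    generate_cohort(generator_config(seed = s))$truth$event_rate
  }, numeric(1))
  expect_gte(mean(rates), 0.547)
  expect_lte(mean(rates), 0.607)
  expect_true(all(abs(rates - 0.577) < 4 * sqrt(0.577 * 0.423 / 589)))
  co <- generate_cohort(generator_config(seed = 9))
  expect_equal(co$config$n_patients, 589L)
  # calibration tolerance on the mean response itself
  expect_lt(abs(mean(plogis(co$truth$intercept + co$truth$linear_predictor)) -
                  0.577), 1e-4)
})

test_that("a planted effect is recoverable by an independent logistic fit", {
  co <- generate_cohort(generator_config(
    n_patients = 500, seed = 21, missingness_rate = 0,
    effect_vector = c(baseline_monocyte = 2.0)))
  x <- scale(co$data$baseline_monocyte)[, 1]
  beta <- newton_logistic(matrix(x, ncol = 1), co$data$lymphopenia)
  expect_gt(beta[2], 0.5)
  # dichotomised at the median the univariate OR exceeds 1
  hi <- ifelse(co$data$baseline_monocyte > median(co$data$baseline_monocyte),
               "high", "low")
  res <- fit_univariate(co$data$lymphopenia, hi, reference = "low")
  expect_gt(res$odds_ratio, 1)
  # glm-based fitter agrees with the hand-rolled Newton solver
  cont <- fit_univariate(co$data$lymphopenia, x)
  expect_equal(log(cont$odds_ratio), beta[2], tolerance = 1e-6)
})

test_that("dose metrics stay above the pairwise correlation floor", {
  mins <- vapply(1:20, function(r) {
    co <- generate_cohort(generator_config(seed = 300 + r))
    cc <- cor(co$data[, co$config$dose_metric_spec$name],
              use = "pairwise.complete.obs")
    min(cc[lower.tri(cc)])
  }, numeric(1))
  expect_gte(mean(mins >= 0.18), 0.95)
})

test_that("outcome agrees with CTCAE grading of the post-RT count", {
  co <- generate_cohort(generator_config(n_patients = 300, seed = 8))
  g <- grade_lymphopenia(co$data$post_rt_lymphocytes, co$config$lln)
  expect_identical(as.integer(g >= 1), co$data$lymphopenia)
})

test_that("dose catalog passes the configured values through", {
  spec1 <- data.frame(name = "single_metric", dose_gy = 4.0, volume = 10.0,
                      volume_link_sign = 1, volume_unit = "L")
  cat1 <- generate_dose_catalog(generator_config(dose_metric_spec = spec1))
  expect_equal(nrow(cat1), 1L)
  expect_equal(cat1$dose_gy, 4.0)
  expect_equal(cat1$volume, 10.0)

  # whole-body integral dose is stored at its representative 4 Gy
  cat_def <- generate_dose_catalog(generator_config())
  expect_equal(cat_def$dose_gy[cat_def$metric == "integral_body_dose"], 4.0)
})

test_that("per-metric volume-dose rank correlation matches the configured sign", {
  spec <- default_dose_metric_spec()
  spec$volume_link_sign <- rep(c(1, -1, 1), 3)
  co <- generate_cohort(generator_config(seed = 17, dose_metric_spec = spec))
  for (j in seq_len(nrow(spec))) {
    sub <- co$dvh[co$dvh$metric == spec$name[j], ]
    rho <- cor(sub$dose_gy, sub$volume, method = "spearman")
    expect_equal(sign(rho), spec$volume_link_sign[j],
                 label = paste("sign for", spec$name[j]))
  }
})

test_that("missingness is MCAR on continuous features only", {
  co <- generate_cohort(generator_config(n_patients = 400, seed = 33,
                                         missingness_rate = 0.1))
  cont <- co$schema$name[co$schema$kind == "continuous"]
  cats <- co$schema$name[co$schema$kind == "categorical"]
  miss_cont <- mean(is.na(as.matrix(co$data[, cont])))
  expect_gt(miss_cont, 0.05)
  expect_lt(miss_cont, 0.15)
  expect_false(anyNA(co$data[, cats]))
  expect_false(anyNA(co$data$lymphopenia))
})
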