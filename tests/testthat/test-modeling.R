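test_that("resampling plans implement the 80% draw and 7:3 split", {
  set.seed(1)
  y <- rbinom(589, 1, 0.577)
  plans <- make_plans(589, B = 5, seed = 3, outcome = y)
  expect_length(plans, 5L)
  for (p in plans) {
    expect_length(p$draw, 471L)            # floor(0.8 * 589)
    expect_length(p$train, 329L)           # floor(0.7 * 471)
    expect_length(p$test, 142L)
    expect_length(intersect(p$train, p$test), 0L)
    expect_setequal(c(p$train, p$test), p$draw)
    # folds partition the training set into 10 non-empty folds
    expect_length(p$folds, length(p$train))
    expect_setequal(unique(p$folds), 1:10)
    # stratification keeps both classes in every fold's training portion
    for (f in 1:10) expect_length(unique(y[p$train][p$folds != f]), 2L)
  }
  expect_identical(make_plans(589, B = 1, seed = 7, outcome = y),
                   make_plans(589, B = 1, seed = 7, outcome = y))
  expect_error(make_plans(589, B = 0), "at least 1")
  expect_error(make_plans(20), "n_patients")
})

test_that("the hyperparameter grid has the stated shape", {
  g <- hyper_grid()
  expect_equal(hyper_grid_size(), 552960)
  expect_equal(hyper_grid_size(), prod(10, 6, 4, 6, 4, 4, 4, 6))
  smp <- hyper_grid_sample(50, seed = 2)
  expect_identical(as.list(smp[1, ]), default_tree_params())
  for (nm in names(g)) {
    expect_true(all(vapply(smp[[nm]],
                           function(v) any(abs(v - g[[nm]]) < 1e-9),
                           logical(1))), label = nm)
  }
})

test_that("tuning returns the single point of a one-point grid", {
  set.seed(30)
  x <- matrix(rnorm(200 * 4), 200, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- rbinom(200, 1, plogis(1.2 * x[, 1]))
  folds <- sample(rep_len(1:5, 200))
  one <- as.data.frame(default_tree_params())
  res <- tune_tree_model(x, y, folds, one, nrounds = 30)
  expect_identical(res$params, as.list(one))
  # with a strong planted effect, CV AUC clears the null model by a margin
  expect_gt(res$cv_auc, 0.5 + 0.1)
})

test_that("full shrinkage zeroes every penalised coefficient", {
  set.seed(31)
  x <- matrix(rnorm(200 * 6), 200, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  y <- rbinom(200, 1, plogis(x[, 1]))
  pen <- fit_penalized(x, y, lambda = 1e6)
  expect_true(all(pen$coef == 0))
  expect_false(any(pen$selected))
})

test_that("penalised selection is sparse under the null, sign-faithful under signal", {
  set.seed(32)
  sel_noise <- replicate(20, {
    x <- matrix(rnorm(400 * 15), 400, 15,
                dimnames = list(NULL, paste0("noise", 1:15)))
    y <- rbinom(400, 1, 0.5)
    suppressWarnings(fit_penalized(x, y, seed = sample.int(1e6, 1))$selected)
  })
  expect_true(all(rowMeans(sel_noise) < 0.5))
  expect_lte(median(colSums(sel_noise)), 5)

  signs <- replicate(20, {
    x <- matrix(rnorm(400 * 5), 400, 5,
                dimnames = list(NULL, paste0("f", 1:5)))
    y <- rbinom(400, 1, plogis(1.5 * x[, 1]))
    sign(fit_penalized(x, y, seed = sample.int(1e6, 1))$coef[["f1"]])
  })
  expect_gte(mean(signs == 1), 0.95)
})

test_that("penalised fits use complete cases only; tree fits use all rows", {
  # few complete rows per CV fold: the penalty search warns, which is fine
  res <- suppressWarnings(tiny_fit(seed = 40, n = 300, B = 1,
                                   fit_lasso = TRUE,
                                   missingness_rate = 0.05))
  mm <- res$mm
  plan <- res$plans[[1]]
  expect_lt(sum(mm$complete), nrow(mm$x))
  pen <- suppressWarnings(suppressMessages(
    fit_penalized(mm$x[plan$train, ], mm$outcome[plan$train])))
  expect_equal(pen$n_complete,
               sum(complete.cases(mm$x[plan$train, ])))
  expect_error(fit_penalized(mm$x[1:25, ], mm$outcome[1:25]),
               "complete-case rows")
})

test_that("the engine is reproducible from seed and config", {
  a <- tiny_fit(seed = 50, n = 250, B = 2)$fit
  b <- tiny_fit(seed = 50, n = 250, B = 2)$fit
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$gain, b$gain)
  expect_identical(a$attributions[[1]]$contrib, b$attributions[[1]]$contrib)
})

test_that("gain and frequency indices are normalised per model", {
  fit <- tiny_fit(seed = 51, n = 250, B = 2)$fit
  expect_equal(unname(rowSums(fit$gain)), rep(1, 2), tolerance = 1e-6)
  expect_equal(unname(rowSums(fit$frequency)), rep(1, 2), tolerance = 1e-6)
  expect_true(all(fit$gain >= 0) && all(fit$frequency >= 0))
})

test_that("group models rank a planted blood signal above clinical noise", {
  eff <- c(baseline_lymphocyte = -1.5, baseline_platelet = 1.0)
  co <- generate_cohort(generator_config(n_patients = 350, seed = 60,
                                         missingness_rate = 0,
                                         effect_vector = eff))
  cv <- generate_cohort(generator_config(n_patients = 200, seed = 61,
                                         missingness_rate = 0,
                                         effect_vector = eff))
  mm <- encode_cohort(co); mv <- encode_cohort(cv)
  plans <- make_plans(nrow(mm$x), B = 3, seed = 62, outcome = mm$outcome)
  res <- run_group_models(mm, plans, nrounds = 60, validation = mv,
                          fit_lasso = FALSE)
  s <- res$summary
  med <- function(grp, coh) {
    s$median[s$group == grp & s$model == "xgboost" & s$metric == "roc_auc" &
               s$cohort == coh]
  }
  expect_gte(med("blood", "validation"), med("clinical", "validation") + 0.1)
  # the full model is no worse than the best single group (within noise)
  best_group <- max(vapply(c("clinical", "tumor", "blood", "radiotherapy",
                             "treatment"), med, numeric(1), coh = "test"))
  expect_gte(med("full", "test"), best_group - 0.02)
  # 6 views x 2 cohorts for one learner
  expect_equal(nrow(unique(s[s$model == "xgboost", c("group", "cohort")])), 12)
})
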