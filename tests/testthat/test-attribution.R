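fake_attribution <- function(contrib, base = rep(0, nrow(contrib))) {
  structure(list(contrib = contrib, base = base, patient_id = NULL),
            class = "ril_attribution")
}

test_that("a single-split model attributes only its split feature", {
  set.seed(80)
  x <- matrix(rnorm(300 * 3), 300, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- as.integer(x[, 1] > 0)
  stump <- fit_tree_model(x, y, params = list(
    learning_rate = 0.5, gamma = 0, max_depth = 1, scale_pos_weight = 1,
    subsample = 1, colsample_bytree = 1, min_child_weight = 1,
    max_delta_step = 0), nrounds = 1)
  a <- per_instance_attributions(stump, x)
  expect_true(all(a$contrib[, c("f2", "f3")] == 0))
  expect_gt(max(abs(a$contrib[, "f1"])), 0)
})

test_that("tree-path attributions equal brute-force Shapley values", {
  x <- as.matrix(expand.grid(f1 = 0:1, f2 = 0:1, f3 = 0:1))
  x <- x[rep(1:8, 5), ]
  y <- as.integer((x[, 1] == 1 & x[, 2] == 1) | x[, 3] == 1)
  m <- fit_tree_model(x, y, params = list(
    learning_rate = 0.3, gamma = 0, max_depth = 2, scale_pos_weight = 1,
    subsample = 1, colsample_bytree = 1, min_child_weight = 1,
    max_delta_step = 0), nrounds = 3)
  a <- per_instance_attributions(m, x[1:8, ])
  for (i in 1:8) {
    oracle <- brute_shapley(m, as.list(as.data.frame(x)[i, ]), colnames(x))
    expect_equal(unname(a$contrib[i, ]), unname(oracle[colnames(x)]),
                 tolerance = 1e-6)
  }
})

test_that("local accuracy: base plus attribution row sums give the raw score", {
  res <- tiny_fit(seed = 81, n = 250, B = 1)
  fit <- res$fit
  plan <- res$plans[[1]]
  model <- fit_tree_model(res$mm$x[plan$train, ], res$mm$outcome[plan$train],
                          nrounds = 50, seed = plan$seed)
  xs <- res$mm$x[plan$test, ]
  a <- per_instance_attributions(model, xs)
  marg <- predict(model, xgboost::xgb.DMatrix(xs, missing = NA),
                  outputmargin = TRUE)
  expect_lt(max(abs(rowSums(a$contrib) + a$base - marg)), 1e-4)
})

test_that("attribution rejects a mismatched column set", {
  res <- tiny_fit(seed = 82, n = 250, B = 1)
  plan <- res$plans[[1]]
  model <- fit_tree_model(res$mm$x[plan$train, ], res$mm$outcome[plan$train],
                          nrounds = 10, seed = 1)
  bad <- res$mm$x[plan$test, -1]
  expect_error(per_instance_attributions(model, bad), "column set")
})

test_that("importance is |.|-before-mean, averaged within then across iterations", {
  z <- fake_attribution(matrix(0, 4, 2, dimnames = list(NULL, c("a", "b"))))
  expect_equal(summarize_importance(list(z)), c(a = 0, b = 0))
  one <- fake_attribution(matrix(c(-2, 2, 0, 0), 2, 2,
                                 dimnames = list(NULL, c("a", "b"))))
  expect_equal(summarize_importance(list(one)), c(a = 2, b = 0))
  two <- fake_attribution(matrix(c(1, 1, 0, 0), 2, 2,
                                 dimnames = list(NULL, c("a", "b"))))
  expect_equal(summarize_importance(list(one, two)), c(a = 1.5, b = 0))
})

test_that("outcome-mode direction hits the trivial anchors", {
  y <- c(0, 1, 0, 1, 1, 0)
  a <- fake_attribution(matrix(c(y, -y, rep(0.7, 6)), 6, 3,
                               dimnames = list(NULL, c("same", "anti", "flat"))))
  d <- direction_score(list(a), list(y), mode = "outcome")
  expect_equal(unname(d), c(1, -1, 0))
  # flipping outcome labels flips every direction sign exactly
  d_flip <- direction_score(list(a), list(1 - y), mode = "outcome")
  expect_equal(d_flip, -d)
})

test_that("feature-mode direction recovers a protective plant", {
  res <- tiny_fit(seed = 83, n = 400, B = 3,
                  effect_vector = c(baseline_lymphocyte = -1.5))
  s <- attribution_summary(res$fit)
  expect_lt(s$direction[s$feature == "baseline_lymphocyte"], -0.5)
  expect_equal(s$feature[1], "baseline_lymphocyte")
})

test_that("direction is zero for features never used by any model", {
  res <- tiny_fit(seed = 84, n = 250, B = 2)
  s <- attribution_summary(res$fit)
  unused <- s$mean_abs_shap == 0
  expect_true(any(unused))
  expect_true(all(s$direction[unused] == 0))
})

test_that("the attribution graph mirrors the summary", {
  s <- structure(data.frame(
    feature = c("f_pos", "f_neg", "f_zero"),
    mean_abs_shap = c(2, 1, 0),
    direction = c(0.8, -0.6, 0),
    mean_gain = NA, mean_frequency = NA, lasso_coef = NA,
    lasso_selection_freq = NA, lasso_p = NA,
    stringsAsFactors = FALSE),
    class = c("ril_attribution_summary", "data.frame"))
  path <- withr::local_tempfile(fileext = ".graphml")
  export_attribution_graph(s, path = path)
  g <- igraph::read_graph(path, format = "graphml")
  # zero-importance features are excluded: 2 features + outcome node
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(igraph::ecount(g), 2L)
  ed <- igraph::as_data_frame(g, what = "edges")
  ed$feature <- ifelse(ed$from == "lymphopenia", ed$to, ed$from)
  expect_equal(ed$sign[match(c("f_pos", "f_neg"), ed$feature)], c(1, -1))
  expect_equal(ed$weight[match(c("f_pos", "f_neg"), ed$feature)], c(0.8, 0.6))
})
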