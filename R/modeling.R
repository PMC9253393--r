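#' Shipped default gradient-boosting configuration
#'
#' The tuned hyperparameter configuration shipped as the fast path, so the
#' full grid search is optional: `learning_rate = 0.04`, `gamma = 5`,
#' `max_depth = 3`, `scale_pos_weight = 1.8`, `subsample = 0.8`,
#' `colsample_bytree = 0.7`, `min_child_weight = 5`, `max_delta_step = 1`.
#'
#' @return Named list of hyperparameters.
#' @export
default_tree_params <- function() {
  list(learning_rate = 0.04, gamma = 5, max_depth = 3, scale_pos_weight = 1.8,
       subsample = 0.8, colsample_bytree = 0.7, min_child_weight = 5,
       max_delta_step = 1)
}

#' Hyperparameter grid definition
#'
#' The stated search ranges: learning_rate 0.01..0.1 step 0.01, gamma 0..5
#' step 1, max_depth 3..6, scale_pos_weight 1..2 step 0.2, subsample and
#' colsample_bytree 0.7..1 step 0.1, min_child_weight 3..6, max_delta_step
#' 0..5. The full Cartesian grid has 552,960 points; [hyper_grid_sample()]
#' draws a randomized subset for desk-scale runs.
#'
#' @return Named list of value vectors, one per hyperparameter.
#' @export
hyper_grid <- function() {
  list(learning_rate = seq(0.01, 0.1, by = 0.01),
       gamma = 0:5,
       max_depth = 3:6,
       scale_pos_weight = seq(1, 2, by = 0.2),
       subsample = seq(0.7, 1, by = 0.1),
       colsample_bytree = seq(0.7, 1, by = 0.1),
       min_child_weight = 3:6,
       max_delta_step = 0:5)
}

#' Cardinality of the full hyperparameter grid
#' @return Integer product of the per-dimension range sizes.
#' @export
hyper_grid_size <- function() prod(vapply(hyper_grid(), length, 1L))

#' Randomized subset of the hyperparameter grid
#'
#' Samples each dimension independently and uniformly from its stated range;
#' the shipped default configuration is always included (first row) so the
#' randomized search can never do worse than the fast path on the CV
#' criterion.
#'
#' @param n Number of random configurations (default 200).
#' @param seed Integer seed.
#' @param include_default Prepend [default_tree_params()] (default `TRUE`).
#' @return Data.frame with one row per configuration.
#' @export
hyper_grid_sample <- function(n = 200, seed = 1L, include_default = TRUE) {
  stopifnot(n >= 1)
  set.seed(seed)
  g <- hyper_grid()
  draws <- as.data.frame(lapply(g, function(v) sample(v, n, replace = TRUE)))
  if (include_default) {
    draws <- rbind(as.data.frame(default_tree_params()), draws)
  }
  unique(draws)
}

#' Build resampling plans for the bootstrap x CV engine
#'
#' For each of `B` iterations: an 80% draw of patients (without replacement by
#' default, despite the procedure's conventional "bootstrapping" name; a
#' with-replacement option is provided), a 7:3 train/test split stratified by
#' outcome, and a stratified k-fold assignment (k = 10) on the training set.
#' Per-plan seeds are derived deterministically from the base seed.
#'
#' @param n_patients Cohort size (>= 50).
#' @param B Number of iterations (default 100).
#' @param seed Base integer seed.
#' @param outcome Optional 0/1 vector of length `n_patients` used to stratify
#'   the split and folds; unstratified when omitted.
#' @param draw_fraction Fraction of patients drawn per iteration
#'   (default 0.8).
#' @param train_fraction Train share of the draw (default 0.7).
#' @param k Number of CV folds on the training set (default 10).
#' @param replace Draw with replacement (default `FALSE`).
#' @return List of `B` plans; each has `iteration`, `seed`, `draw`, `train`,
#'   `test` (absolute patient indices) and `folds` (fold id per training row).
#' @export
make_plans <- function(n_patients, B = 100, seed = 1L, outcome = NULL,
                       draw_fraction = 0.8, train_fraction = 0.7, k = 10,
                       replace = FALSE) {
  stopifnot(is_scalar_number(n_patients), n_patients >= 50)
  if (!is_scalar_number(B) || B < 1) stop_bad_arg("B must be at least 1")
  if (!is.null(outcome)) stopifnot(length(outcome) == n_patients)
  lapply(seq_len(B), function(b) {
    seed_b <- derive_seed(seed, b)
    set.seed(seed_b)
    draw <- sort(sample.int(n_patients, floor(draw_fraction * n_patients),
                            replace = replace))
    n_train <- floor(train_fraction * length(draw))
    if (is.null(outcome)) {
      train <- sort(sample(draw, n_train))
    } else {
      train <- stratified_take(draw, outcome[draw], n_train)
    }
    test <- setdiff(draw, train)
    folds <- if (is.null(outcome)) {
      sample(rep_len(seq_len(k), length(train)))
    } else {
      stratified_folds(outcome[train], k)
    }
    list(iteration = b, seed = seed_b, draw = draw, train = train,
         test = test, folds = folds)
  })
}

# Take n_total indices stratified by class, proportional allocation.
stratified_take <- function(idx, strata, n_total) {
  classes <- sort(unique(strata))
  sizes <- vapply(classes, function(cl) sum(strata == cl), 1L)
  take <- floor(n_total * sizes / length(idx))
  short <- n_total - sum(take)
  if (short > 0) {
    extra <- order(sizes, decreasing = TRUE)[seq_len(short)]
    take[extra] <- take[extra] + 1L
  }
  out <- unlist(lapply(seq_along(classes), function(i) {
    pool <- idx[strata == classes[i]]
    sample(pool, min(take[i], length(pool)))
  }))
  sort(out)
}

stratified_folds <- function(strata, k) {
  folds <- integer(length(strata))
  for (cl in unique(strata)) {
    rows <- which(strata == cl)
    folds[rows] <- sample(rep_len(seq_len(k), length(rows)))
  }
  folds
}

as_xgb_params <- function(params, seed = 0L) {
  list(objective = "binary:logistic", eval_metric = "logloss", nthread = 1,
       seed = seed,
       eta = params$learning_rate, gamma = params$gamma,
       max_depth = params$max_depth,
       scale_pos_weight = params$scale_pos_weight,
       subsample = params$subsample,
       colsample_bytree = params$colsample_bytree,
       min_child_weight = params$min_child_weight,
       max_delta_step = params$max_delta_step)
}

#' Fit a gradient-boosted tree model
#'
#' Trains a binary-logistic boosted tree ensemble on a numeric matrix with
#' native missing-value handling (all rows are used, `NA` included).
#'
#' @param x Numeric feature matrix (may contain `NA`).
#' @param y 0/1 outcome vector.
#' @param params Hyperparameter list as [default_tree_params()].
#' @param nrounds Number of boosting rounds (default 200).
#' @param seed Seed for the learner's subsampling.
#' @return An `xgb.Booster`.
#' @export
fit_tree_model <- function(x, y, params = default_tree_params(),
                           nrounds = 200, seed = 0L) {
  stopifnot(is.matrix(x), length(y) == nrow(x), all(y %in% c(0, 1)))
  dtrain <- xgboost::xgb.DMatrix(x, label = y, missing = NA)
  xgboost::xgb.train(params = as_xgb_params(params, seed), data = dtrain,
                     nrounds = nrounds, verbose = 0)
}

#' Predict event probabilities from a tree model
#' @param model An `xgb.Booster`.
#' @param x Numeric feature matrix with the model's columns.
#' @return Vector of probabilities.
#' @export
predict_tree <- function(model, x) {
  predict(model, xgboost::xgb.DMatrix(x, missing = NA))
}

#' Tune the tree model by k-fold cross-validated ROC-AUC
#'
#' Evaluates each grid configuration by mean held-fold ROC-AUC over the
#' supplied fold assignment and returns the maximizer. Folds whose training
#' portion is single-class are skipped with a message; ties on CV AUC are
#' broken by lower `max_depth`, then lower `learning_rate`, then first seen.
#'
#' @param x,y Training feature matrix and 0/1 outcome.
#' @param folds Fold id per row of `x`.
#' @param grid Data.frame of configurations (e.g. [hyper_grid_sample()]).
#' @param nrounds Boosting rounds per fit (default 200).
#' @param seed Seed for subsampling inside fold fits.
#' @return List with `params` (chosen configuration as a list), `cv_auc` and
#'   `table` (per-configuration mean CV AUC).
#' @export
tune_tree_model <- function(x, y, folds, grid, nrounds = 200, seed = 0L) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1,
            length(folds) == nrow(x))
  usable <- Filter(function(f) length(unique(y[folds != f])) == 2,
                   sort(unique(folds)))
  skipped <- setdiff(sort(unique(folds)), usable)
  if (length(skipped)) {
    message("skipping degenerate fold(s): ", paste(skipped, collapse = ", "))
  }
  if (!length(usable)) stop_bad_arg("all folds are degenerate")
  cv_auc <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- as.list(grid[i, , drop = FALSE])
    aucs <- vapply(usable, function(f) {
      fit <- fit_tree_model(x[folds != f, , drop = FALSE], y[folds != f],
                            params = cfg, nrounds = nrounds, seed = seed)
      roc_auc(predict_tree(fit, x[folds == f, , drop = FALSE]), y[folds == f])
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  best <- max(cv_auc)
  cand <- which(cv_auc >= best - 1e-12)
  cand <- cand[order(grid$max_depth[cand], grid$learning_rate[cand], cand)]
  chosen <- cand[1]
  list(params = as.list(grid[chosen, , drop = FALSE]),
       cv_auc = cv_auc[chosen],
       table = cbind(grid, cv_auc = cv_auc))
}

#' Fit the L1-penalised logistic regression on complete cases
#'
#' Restricts to complete-case rows, drops constant columns (with a message),
#' standardises inside the fitter and chooses the penalty on the
#' cross-validated ROC-AUC path. The default `rule = "1se"` takes the largest
#' penalty whose CV AUC lies within one standard error of the maximum — the
#' standard parsimony rule, which keeps null features out of the model and
#' yields the heavily sparse coefficient profiles this analysis compares
#' against; `rule = "min"` takes the AUC-maximising penalty itself. Zero
#' coefficients are recorded as not-selected.
#'
#' @param x Numeric feature matrix (rows with any `NA` are excluded).
#' @param y 0/1 outcome aligned to `x`.
#' @param seed Seed for the CV fold draw.
#' @param nfolds CV folds for the penalty search (default 10).
#' @param lambda Optional fixed penalty overriding the CV search.
#' @param rule Penalty rule on the CV-AUC path: `"1se"` (default) or `"min"`.
#' @return List with `coef` (named vector over all columns of `x`, zeros where
#'   unselected), `intercept`, `selected` (logical), `lambda`, `cv_auc`
#'   (`NA` for a fixed penalty) and `dropped` (constant columns).
#' @export
fit_penalized <- function(x, y, seed = 0L, nfolds = 10, lambda = NULL,
                          rule = c("1se", "min")) {
  rule <- match.arg(rule)
  stopifnot(is.matrix(x), length(y) == nrow(x))
  cc <- complete.cases(x)
  x_cc <- x[cc, , drop = FALSE]; y_cc <- y[cc]
  if (min(table(factor(y_cc, levels = 0:1))) < 10) {
    stop_bad_arg("need at least 10 complete-case rows per class")
  }
  const <- apply(x_cc, 2, function(v) length(unique(v)) <= 1)
  if (any(const)) {
    message("dropping constant column(s): ",
            paste(colnames(x_cc)[const], collapse = ", "))
  }
  x_fit <- x_cc[, !const, drop = FALSE]
  set.seed(seed)
  if (is.null(lambda)) {
    cv <- glmnet::cv.glmnet(x_fit, y_cc, family = "binomial",
                            type.measure = "auc", nfolds = nfolds,
                            standardize = TRUE)
    lam <- if (rule == "1se") cv$lambda.1se else cv$lambda.min
    cv_auc <- cv$cvm[match(lam, cv$lambda)]
    fit <- cv$glmnet.fit
  } else {
    fit <- glmnet::glmnet(x_fit, y_cc, family = "binomial",
                          standardize = TRUE, lambda = lambda)
    lam <- lambda
    cv_auc <- NA_real_
  }
  beta <- as.numeric(coef(fit, s = lam))
  names(beta) <- rownames(coef(fit, s = lam))
  full <- setNames(numeric(ncol(x)), colnames(x))
  full[names(beta)[-1][names(beta)[-1] %in% names(full)]] <-
    beta[-1][names(beta)[-1] %in% names(full)]
  list(coef = full, intercept = beta[1], selected = full != 0,
       lambda = lam, cv_auc = cv_auc, dropped = colnames(x_cc)[const],
       n_complete = sum(cc))
}

predict_penalized <- function(pen, x) {
  plogis(pen$intercept + as.numeric(x %*% pen$coef))
}

#' Run the bootstrap x cross-validation training engine
#'
#' Executes the supplied resampling plans: per iteration the tree model is
#' (optionally grid-tuned then) fitted on the training split with all rows
#' including missing values, evaluated on the iteration's test split and on an
#' optional external validation cohort; the penalised regression is fitted and
#' evaluated on complete cases only. Per-feature gain and frequency indices
#' and exact per-instance attributions on the test split are collected for the
#' attribution analysis.
#'
#' @param mm A `ril_model_matrix` from [encode_cohort()].
#' @param plans Plans from [make_plans()].
#' @param params Tree hyperparameters used when `grid` is `NULL`.
#' @param grid Optional data.frame of configurations to tune per iteration.
#' @param nrounds Boosting rounds (default 200).
#' @param threshold Classification threshold (default 0.5).
#' @param validation Optional `ril_model_matrix` external validation cohort
#'   with the same columns.
#' @param fit_lasso Also fit the penalised regression (default `TRUE`).
#' @param compute_shap Collect per-instance attributions on the test split
#'   (default `TRUE`).
#' @return Object of class `ril_fit`: `metrics` (long data.frame: iteration,
#'   model, cohort, six metrics), `gain` and `frequency` (B x p matrices),
#'   `lasso_coef` (B x p, zeros where unselected), `lasso_selected`,
#'   `attributions` + `attribution_outcomes` (per-iteration), `params`
#'   (per-iteration tree configuration) and `feature_names`.
#' @export
run_bootstrap_models <- function(mm, plans, params = default_tree_params(),
                                 grid = NULL, nrounds = 200, threshold = 0.5,
                                 validation = NULL, fit_lasso = TRUE,
                                 compute_shap = TRUE) {
  stopifnot(inherits(mm, "ril_model_matrix"))
  p <- ncol(mm$x); B <- length(plans)
  feats <- colnames(mm$x)
  if (!is.null(validation)) {
    stopifnot(inherits(validation, "ril_model_matrix"),
              setequal(colnames(validation$x), feats))
    xv <- validation$x[, feats, drop = FALSE]
  }
  gain <- freq <- matrix(0, B, p, dimnames = list(NULL, feats))
  lasso_coef <- matrix(NA_real_, B, p, dimnames = list(NULL, feats))
  metrics <- list(); attributions <- list(); attr_outcomes <- list()
  attr_features <- list(); chosen_params <- list()

  for (plan in plans) {
    b <- plan$iteration
    xt <- mm$x[plan$train, , drop = FALSE]; yt <- mm$outcome[plan$train]
    xs <- mm$x[plan$test, , drop = FALSE];  ys <- mm$outcome[plan$test]
    cfg <- if (is.null(grid)) params else {
      tune_tree_model(xt, yt, plan$folds, grid, nrounds = nrounds,
                      seed = plan$seed)$params
    }
    chosen_params[[b]] <- cfg
    model <- fit_tree_model(xt, yt, params = cfg, nrounds = nrounds,
                            seed = plan$seed)
    metrics[[length(metrics) + 1L]] <-
      cbind(iteration = b, model = "xgboost", cohort = "test",
            evaluate_scores(predict_tree(model, xs), ys, threshold))
    if (!is.null(validation)) {
      metrics[[length(metrics) + 1L]] <-
        cbind(iteration = b, model = "xgboost", cohort = "validation",
              evaluate_scores(predict_tree(model, xv), validation$outcome,
                              threshold))
    }
    imp <- xgboost::xgb.importance(model = model)
    if (!is.null(imp) && nrow(imp)) {
      gain[b, imp$Feature] <- imp$Gain
      freq[b, imp$Feature] <- imp$Frequency
    }
    if (compute_shap) {
      attributions[[b]] <- per_instance_attributions(model, xs)
      attr_outcomes[[b]] <- ys
      attr_features[[b]] <- xs
    }
    if (fit_lasso) {
      pen <- try(fit_penalized(xt, yt, seed = plan$seed), silent = TRUE)
      if (!inherits(pen, "try-error")) {
        lasso_coef[b, ] <- pen$coef
        cc <- complete.cases(xs)
        if (sum(cc) && length(unique(ys[cc])) == 2) {
          metrics[[length(metrics) + 1L]] <-
            cbind(iteration = b, model = "lasso", cohort = "test",
                  evaluate_scores(predict_penalized(pen, xs[cc, , drop = FALSE]),
                                  ys[cc], threshold))
        }
        if (!is.null(validation)) {
          ccv <- complete.cases(xv)
          metrics[[length(metrics) + 1L]] <-
            cbind(iteration = b, model = "lasso", cohort = "validation",
                  evaluate_scores(predict_penalized(pen, xv[ccv, , drop = FALSE]),
                                  validation$outcome[ccv], threshold))
        }
      } else {
        message("iteration ", b, ": penalised fit skipped (",
                conditionMessage(attr(pen, "condition")), ")")
      }
    }
  }
  structure(list(metrics = do.call(rbind, metrics), gain = gain,
                 frequency = freq, lasso_coef = lasso_coef,
                 lasso_selected = !is.na(lasso_coef) & lasso_coef != 0,
                 attributions = attributions,
                 attribution_outcomes = attr_outcomes,
                 attribution_features = attr_features,
                 params = chosen_params, feature_names = feats,
                 threshold = threshold),
            class = "ril_fit")
}

#' Summarise metric distributions of a fitted engine
#'
#' @param fit A `ril_fit`.
#' @return Data.frame with median and quartiles per model, cohort and metric.
#' @export
summarize_metrics <- function(fit) {
  stopifnot(inherits(fit, "ril_fit"))
  m <- fit$metrics
  metric_cols <- c("sensitivity", "specificity", "accuracy", "f1",
                   "roc_auc", "pr_auc")
  out <- list()
  for (mod in unique(m$model)) for (coh in unique(m$cohort)) {
    sub <- m[m$model == mod & m$cohort == coh, metric_cols, drop = FALSE]
    if (!nrow(sub)) next
    for (mc in metric_cols) {
      v <- sub[[mc]]
      out[[length(out) + 1L]] <- data.frame(
        model = mod, cohort = coh, metric = mc,
        median = median(v, na.rm = TRUE),
        q1 = unname(quantile(v, 0.25, na.rm = TRUE)),
        q3 = unname(quantile(v, 0.75, na.rm = TRUE)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Fit the engine on the full matrix and on each feature-group view
#'
#' Runs [run_bootstrap_models()] on the full model matrix and on the five
#' column-disjoint group views; groups with zero columns are skipped with a
#' message. Attribution collection is disabled for the group runs.
#'
#' @inheritParams run_bootstrap_models
#' @param validation Optional external validation `ril_model_matrix` (split
#'   into matching group views internally).
#' @return List with `fits` (named list of `ril_fit`, `"full"` first) and
#'   `summary` (stacked [summarize_metrics()] with a `group` column).
#' @export
run_group_models <- function(mm, plans, params = default_tree_params(),
                             grid = NULL, nrounds = 200, threshold = 0.5,
                             validation = NULL, fit_lasso = TRUE) {
  views <- c(list(full = mm), split_groups(mm))
  valid_views <- if (is.null(validation)) NULL else {
    c(list(full = validation), split_groups(validation))
  }
  fits <- list(); summaries <- list()
  for (g in names(views)) {
    if (!ncol(views[[g]]$x)) {
      message("skipping empty feature group: ", g)
      next
    }
    fits[[g]] <- run_bootstrap_models(
      views[[g]], plans, params = params, grid = grid, nrounds = nrounds,
      threshold = threshold,
      validation = if (is.null(valid_views)) NULL else valid_views[[g]],
      fit_lasso = fit_lasso, compute_shap = (g == "full"))
    summaries[[g]] <- cbind(group = g, summarize_metrics(fits[[g]]))
  }
  list(fits = fits, summary = do.call(rbind, summaries))
}
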