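# Independent oracles used across the suite. These deliberately re-derive
# quantities by a different route than the package code they check.

# --- logistic regression by hand-rolled Newton-Raphson (IRLS) ---------------
newton_logistic <- function(X, y, tol = 1e-12, maxit = 100) {
  X <- cbind(1, X)
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- plogis(eta)
    W <- mu * (1 - mu)
    score <- crossprod(X, y - mu)
    info <- crossprod(X * W, X)
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  as.numeric(beta)
}

# --- brute-force Shapley values over a fitted tree ensemble -----------------
# The coalition value v(S) follows the tree with observed values for features
# in S and averages both branches by their cover weights otherwise; Shapley
# values are then computed by exhaustive subset enumeration.
booster_trees <- function(model) {
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = model))
  split(dt, dt$Tree)
}

tree_expect <- function(tree, x, S) {
  rec <- function(node_id) {
    row <- tree[tree$ID == node_id, , drop = FALSE]
    if (row$Feature == "Leaf") return(row$Gain)
    if (row$Feature %in% S) {
      v <- x[[row$Feature]]
      if (is.na(v)) return(rec(row$Missing))
      if (v < row$Split) rec(row$Yes) else rec(row$No)
    } else {
      wy <- tree$Cover[tree$ID == row$Yes]
      wn <- tree$Cover[tree$ID == row$No]
      (wy * rec(row$Yes) + wn * rec(row$No)) / (wy + wn)
    }
  }
  rec(tree$ID[tree$Node == 0])
}

brute_shapley <- function(model, x, features) {
  trees <- booster_trees(model)
  v <- function(S) sum(vapply(trees, tree_expect, numeric(1), x = x, S = S))
  n <- length(features)
  out <- vapply(features, function(f) {
    others <- setdiff(features, f)
    total <- 0
    for (k in 0:length(others)) {
      combs <- if (k == 0) list(character()) else
        utils::combn(others, k, simplify = FALSE)
      for (S in combs) {
        w <- factorial(length(S)) * factorial(n - length(S) - 1) / factorial(n)
        total <- total + w * (v(c(S, f)) - v(S))
      }
    }
    total
  }, numeric(1))
  names(out) <- features
  out
}

# --- discrepancy formula, written independently as a plain loop -------------
discrepancy_oracle <- function(a, b, important, f_max) {
  acc <- 0
  for (f in important) {
    acc <- acc + abs(a[[f]] - b[[f]]) / f_max[[f]]
  }
  acc / length(important)
}

# --- hand-built model matrix ------------------------------------------------
make_matrix_fixture <- function(x, outcome,
                                ids = sprintf("P%03d", seq_len(nrow(x)))) {
  rownames(x) <- ids
  structure(list(x = x, outcome = outcome, patient_id = ids,
                 complete = complete.cases(x),
                 columns = data.frame(column = colnames(x),
                                      feature = colnames(x),
                                      level = NA_character_, group = "blood",
                                      stringsAsFactors = FALSE)),
            class = "ril_model_matrix")
}

# --- small cohort fixtures --------------------------------------------------
tiny_generator <- function(seed = 1, n = 200, missingness_rate = 0, ...) {
  generator_config(n_patients = n, seed = seed,
                   missingness_rate = missingness_rate, ...)
}

tiny_fit <- function(seed = 1, n = 250, B = 2, fit_lasso = FALSE, ...) {
  co <- generate_cohort(tiny_generator(seed = seed, n = n, ...))
  mm <- encode_cohort(co)
  plans <- make_plans(nrow(mm$x), B = B, seed = seed + 1, outcome = mm$outcome)
  fit <- run_bootstrap_models(mm, plans, fit_lasso = fit_lasso, nrounds = 50)
  list(cohort = co, mm = mm, plans = plans, fit = fit)
}
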