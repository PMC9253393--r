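#' Exact per-instance tree attributions
#'
#' Computes exact tree-path (TreeSHAP) additive attribution values on the
#' log-odds margin for every instance and feature, not a sampling
#' approximation. Local accuracy holds: for each instance the base value plus
#' the row sum of attributions equals the model's raw (pre-link) prediction.
#'
#' @param model An `xgb.Booster`.
#' @param x Numeric matrix whose columns match the model's features.
#' @return Object of class `ril_attribution`: list with `contrib` (instances x
#'   features matrix of attribution values), `base` (per-instance base value)
#'   and `patient_id` (row names of `x`, if any).
#' @export
per_instance_attributions <- function(model, x) {
  stopifnot(inherits(model, "xgb.Booster"), is.matrix(x))
  feats <- xgboost::getinfo(model, "feature_name")
  if (length(feats) && !identical(colnames(x), feats)) {
    bad <- c(setdiff(feats, colnames(x)), setdiff(colnames(x), feats))
    stop_bad_arg("column set does not match the model's features: ",
                 paste(unique(bad), collapse = ", "))
  }
  ctr <- predict(model, xgboost::xgb.DMatrix(x, missing = NA),
                 predcontrib = TRUE)
  base_col <- ncol(ctr)   # bias column is last
  structure(list(contrib = ctr[, -base_col, drop = FALSE],
                 base = ctr[, base_col],
                 patient_id = rownames(x)),
            class = "ril_attribution")
}

#' Mean absolute attribution per feature
#'
#' Averages |attribution| over instances within each resampling iteration,
#' then averages over iterations, yielding the non-negative importance score
#' used to rank features.
#'
#' @param attributions List of `ril_attribution` (one per iteration).
#' @return Named numeric vector of mean |SHAP| per feature.
#' @export
summarize_importance <- function(attributions) {
  stopifnot(length(attributions) >= 1)
  per_iter <- lapply(attributions, function(a) {
    stopifnot(inherits(a, "ril_attribution"))
    colMeans(abs(a$contrib))
  })
  feats <- names(per_iter[[1]])
  stopifnot(all(vapply(per_iter, function(v) identical(names(v), feats),
                       logical(1))))
  colMeans(do.call(rbind, per_iter))
}

#' Directional attribution score
#'
#' The signed direction score in \[-1, 1\]: per iteration, a Spearman rank
#' correlation (average ranks on ties) of a feature's per-instance attribution
#' values; the final score is the mean over iterations. A score near +1 marks
#' a feature that promotes the event, near -1 one that protects against it.
#' Iterations where a feature's attribution column is constant (the feature
#' was not used by that model) contribute 0.
#'
#' Two correlates are available. The default, `mode = "feature"`, correlates
#' each attribution column with the feature's own values: a protective feature
#' (high value pushes the prediction down) then scores negative. The
#' alternative `mode = "outcome"` correlates attributions with the binary
#' outcomes; because a feature's attribution column is a monotone component of
#' the prediction, that score is non-negative for any predictive feature and
#' measures predictiveness rather than direction — it is kept for comparison
#' but cannot recover a protective sign.
#'
#' @param attributions List of `ril_attribution` (one per iteration).
#' @param outcomes List of 0/1 vectors row-aligned to each attribution matrix.
#' @param mode `"feature"` (default) or `"outcome"`, see above.
#' @param feature_values For `mode = "feature"`: list of matrices of feature
#'   values aligned to the attribution rows.
#' @return Named numeric vector of direction scores per feature.
#' @export
direction_score <- function(attributions, outcomes,
                            mode = c("feature", "outcome"),
                            feature_values = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(attributions) == length(outcomes))
  if (mode == "feature") {
    stopifnot(!is.null(feature_values),
              length(feature_values) == length(attributions))
  }
  per_iter <- lapply(seq_along(attributions), function(i) {
    a <- attributions[[i]]
    y <- outcomes[[i]]
    if (length(y) != nrow(a$contrib)) {
      stop_bad_arg("outcome length does not match attribution rows in ",
                   "iteration ", i)
    }
    vapply(colnames(a$contrib), function(f) {
      v <- a$contrib[, f]
      if (sd(v) == 0) return(0)
      target <- if (mode == "outcome") y else feature_values[[i]][, f]
      if (sd(target, na.rm = TRUE) == 0) return(0)
      cor(v, target, method = "spearman", use = "complete.obs")
    }, numeric(1))
  })
  colMeans(do.call(rbind, per_iter))
}

#' Attribution summary table
#'
#' Aggregates a fitted engine into one row per feature: mean |SHAP|
#' importance, direction score, mean gain and frequency indices from the tree
#' models, and the penalised-regression record (mean coefficient across
#' iterations — zeros counted for unselected iterations — its selection
#' frequency, and a two-sided one-sample t-test p-value of the per-iteration
#' coefficients against zero; the shrinkage fit itself has no classical
#' p-value).
#'
#' @param fit A `ril_fit` from [run_bootstrap_models()] with attributions
#'   collected.
#' @param mode Direction mode passed to [direction_score()].
#' @return Data.frame of class `ril_attribution_summary`, sorted by decreasing
#'   mean |SHAP|.
#' @export
attribution_summary <- function(fit, mode = "feature") {
  stopifnot(inherits(fit, "ril_fit"), length(fit$attributions) >= 1)
  imp <- summarize_importance(fit$attributions)
  dir <- direction_score(fit$attributions, fit$attribution_outcomes,
                         mode = mode,
                         feature_values = fit$attribution_features)
  coefs <- fit$lasso_coef
  lasso_mean <- lasso_freq <- lasso_p <- setNames(
    rep(NA_real_, length(imp)), names(imp))
  if (!all(is.na(coefs))) {
    ok <- rowSums(is.na(coefs)) == 0
    coefs <- coefs[ok, , drop = FALSE]
    lasso_mean <- colMeans(coefs)
    lasso_freq <- colMeans(coefs != 0)
    lasso_p <- apply(coefs, 2, function(v) {
      if (sd(v) == 0) return(if (mean(v) == 0) 1 else 0)
      t.test(v)$p.value
    })
  }
  out <- data.frame(feature = names(imp),
                    mean_abs_shap = unname(imp),
                    direction = unname(dir[names(imp)]),
                    mean_gain = unname(colMeans(fit$gain)[names(imp)]),
                    mean_frequency = unname(colMeans(fit$frequency)[names(imp)]),
                    lasso_coef = unname(lasso_mean[names(imp)]),
                    lasso_selection_freq = unname(lasso_freq[names(imp)]),
                    lasso_p = unname(lasso_p[names(imp)]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_abs_shap), ]
  rownames(out) <- NULL
  class(out) <- c("ril_attribution_summary", "data.frame")
  out
}

#' Export the attribution network
#'
#' Builds the feature-contribution graph: one node per feature with positive
#' mean |SHAP| (sized by it), one outcome node, and one edge per feature
#' weighted by |direction| and signed by the direction score. Features never
#' used by any model (mean |SHAP| = 0) are excluded. Written as GraphML.
#'
#' @param summary A `ril_attribution_summary`.
#' @param groups Optional named character vector mapping feature to group,
#'   stored as a node attribute.
#' @param path Output file path; when `NULL` the igraph object is returned
#'   without writing.
#' @param outcome_label Name of the outcome node (default `"lymphopenia"`).
#' @return The igraph object, invisibly when written to `path`.
#' @export
export_attribution_graph <- function(summary, groups = NULL, path = NULL,
                                     outcome_label = "lymphopenia") {
  stopifnot(inherits(summary, "ril_attribution_summary"))
  s <- summary[summary$mean_abs_shap > 0, , drop = FALSE]
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, 1, name = outcome_label, kind = "outcome",
                            size = if (nrow(s)) max(s$mean_abs_shap) else 1,
                            group = "outcome")
  if (nrow(s)) {
    g <- igraph::add_vertices(
      g, nrow(s), name = s$feature, kind = "feature", size = s$mean_abs_shap,
      group = if (is.null(groups)) NA_character_ else
        unname(groups[s$feature]))
    edges <- as.vector(rbind(s$feature, outcome_label))
    g <- igraph::add_edges(g, edges, weight = abs(s$direction),
                           sign = sign(s$direction),
                           direction = s$direction)
  }
  if (!is.null(path)) {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(g))
  }
  g
}
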