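#' Discrepancy between two patients over the important features
#'
#' The mean over the designated important features of the absolute difference
#' scaled by the feature's cohort maximum:
#' `(1/n) * sum_i |f_a,i - f_b,i| / f_max,i`. Symmetric in its arguments and
#' zero exactly when the two patients agree on every important feature.
#'
#' @param a,b Named numeric vectors of feature values.
#' @param important Character vector of important feature names (length >= 1).
#' @param f_max Named vector of positive per-feature cohort maxima.
#' @return Non-negative scalar, `NA` if either patient is missing an important
#'   feature value.
#' @export
pair_discrepancy <- function(a, b, important, f_max) {
  stopifnot(length(important) >= 1,
            all(important %in% names(a)), all(important %in% names(b)),
            all(important %in% names(f_max)))
  if (any(f_max[important] <= 0)) {
    stop_bad_arg("per-feature maxima must be positive")
  }
  va <- a[important]; vb <- b[important]
  if (anyNA(va) || anyNA(vb)) return(NA_real_)
  mean(abs(va - vb) / f_max[important])
}

#' Select matched discordant-outcome pairs under a discrepancy threshold
#'
#' For a probe feature, the important features are those with strictly greater
#' mean |SHAP| than the probe (the probe is never in its own importance set).
#' All discordant-outcome patient pairs with discrepancy strictly below the
#' threshold are candidates; pairs involving a patient with a missing
#' important-feature value are ineligible. Selection is greedy in ascending
#' discrepancy (ties broken by patient identifiers) with no patient reuse.
#'
#' @param mm A `ril_model_matrix` of the cohort (encoded, so categorical
#'   indicator columns have maxima of 1).
#' @param probe Probe (less important) feature column name.
#' @param importance Named mean-|SHAP| vector or a `ril_attribution_summary`.
#' @param threshold Non-negative discrepancy threshold (default 0.10);
#'   discrepancies must fall strictly below it, so a zero threshold always
#'   yields an empty set.
#' @return Object of class `ril_paired_set`: data.frame of pairs (`id_event`,
#'   `id_control`, `discrepancy`) with attributes `probe`, `important`,
#'   `threshold` and `n_candidates`. Zero eligible pairs yields an empty set
#'   with a warning.
#' @export
select_pairs <- function(mm, probe, importance, threshold = 0.10) {
  stopifnot(inherits(mm, "ril_model_matrix"))
  if (inherits(importance, "ril_attribution_summary")) {
    importance <- setNames(importance$mean_abs_shap, importance$feature)
  }
  if (!probe %in% names(importance)) {
    stop_bad_arg("probe feature absent from importance: ", probe)
  }
  if (!is_scalar_number(threshold) || threshold < 0) {
    stop_bad_arg("threshold must be non-negative")
  }
  important <- names(importance)[importance > importance[[probe]]]
  important <- intersect(important, colnames(mm$x))
  if (!length(important)) {
    stop_bad_arg("no features more important than the probe")
  }
  f_max <- apply(mm$x[, important, drop = FALSE], 2, max, na.rm = TRUE)
  if (any(f_max <= 0)) stop_bad_arg("per-feature maxima must be positive")

  xi <- mm$x[, important, drop = FALSE]
  eligible <- rowSums(is.na(xi)) == 0
  cases <- which(eligible & mm$outcome == 1)
  controls <- which(eligible & mm$outcome == 0)
  empty <- data.frame(id_event = character(), id_control = character(),
                      discrepancy = numeric(), stringsAsFactors = FALSE)
  if (!length(cases) || !length(controls)) {
    warning("no eligible discordant pairs", call. = FALSE)
    return(structure(empty, probe = probe, important = important,
                     threshold = threshold, n_candidates = 0L,
                     class = c("ril_paired_set", "data.frame")))
  }
  # accumulate the scaled absolute differences feature by feature
  disc <- matrix(0, length(cases), length(controls))
  for (f in important) {
    disc <- disc + abs(outer(xi[cases, f], xi[controls, f], "-")) / f_max[[f]]
  }
  disc <- disc / length(important)
  cand <- which(disc < threshold, arr.ind = TRUE)
  if (!nrow(cand)) {
    warning("no candidate pairs below the threshold", call. = FALSE)
    return(structure(empty, probe = probe, important = important,
                     threshold = threshold, n_candidates = 0L,
                     class = c("ril_paired_set", "data.frame")))
  }
  ids <- mm$patient_id
  cand_df <- data.frame(case = cases[cand[, 1]],
                        control = controls[cand[, 2]],
                        discrepancy = disc[cand], stringsAsFactors = FALSE)
  cand_df <- cand_df[order(cand_df$discrepancy, ids[cand_df$case],
                           ids[cand_df$control]), ]
  used <- logical(nrow(mm$x))
  keep <- logical(nrow(cand_df))
  for (i in seq_len(nrow(cand_df))) {
    a <- cand_df$case[i]; b <- cand_df$control[i]
    if (!used[a] && !used[b]) {
      keep[i] <- TRUE
      used[a] <- used[b] <- TRUE
    }
  }
  sel <- cand_df[keep, , drop = FALSE]
  out <- data.frame(id_event = ids[sel$case], id_control = ids[sel$control],
                    discrepancy = sel$discrepancy, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, probe = probe, important = important, threshold = threshold,
            n_candidates = nrow(cand_df),
            class = c("ril_paired_set", "data.frame"))
}

#' Paired t-test of the probe feature over matched pairs
#'
#' Two-sided paired t-test on the within-pair differences (value in the
#' lymphopenia member minus value in the non-lymphopenia member) of the probe
#' feature. Pairs with a missing probe value are dropped; zero variance of the
#' differences is reported as degenerate rather than a p-value.
#'
#' @param pairs A `ril_paired_set` from [select_pairs()].
#' @param values Named numeric vector of probe feature values indexed by
#'   patient identifier (e.g. a column of `mm$x` with `mm$patient_id` names).
#' @return List with `t`, `p_value`, `n_pairs`, `mean_event`, `mean_control`,
#'   `mean_difference` and `degenerate`.
#' @export
paired_test <- function(pairs, values) {
  stopifnot(inherits(pairs, "ril_paired_set"), !is.null(names(values)))
  ve <- values[pairs$id_event]; vc <- values[pairs$id_control]
  ok <- !is.na(ve) & !is.na(vc)
  ve <- ve[ok]; vc <- vc[ok]
  if (length(ve) < 2) {
    stop_bad_arg("need at least 2 pairs with non-missing probe values")
  }
  d <- ve - vc
  if (sd(d) == 0) {
    return(list(t = NA_real_, p_value = NA_real_, n_pairs = length(d),
                mean_event = mean(ve), mean_control = mean(vc),
                mean_difference = mean(d), degenerate = TRUE))
  }
  ht <- t.test(ve, vc, paired = TRUE)
  list(t = unname(ht$statistic), p_value = ht$p.value, n_pairs = length(d),
       mean_event = mean(ve), mean_control = mean(vc),
       mean_difference = mean(d), degenerate = FALSE)
}
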