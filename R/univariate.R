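#' Univariate logistic regression for one predictor
#'
#' Fits `outcome ~ predictor` by maximum-likelihood logistic regression and
#' reports the odds ratio with a Wald 95% interval on the log scale. For a
#' categorical predictor one row per non-reference level is returned and the
#' MLE odds ratio of a binary predictor equals the 2x2 cross-product ratio
#' `ad/bc`. Separation (a zero cell against the reference) is flagged and the
#' odds ratio reported as unstable rather than silently corrected, matching
#' how such degenerate rows appear in published cohort tables.
#'
#' @param outcome 0/1 vector with both classes present.
#' @param predictor Numeric vector (continuous, odds ratio per unit on the
#'   native scale) or character/factor (categorical).
#' @param feature Feature name used in the output.
#' @param reference Reference level for categorical predictors (default: first
#'   factor level / alphabetically first).
#' @return Data.frame with columns `feature`, `level`, `n_ref_without`,
#'   `n_ref_with`, `n_without`, `n_with`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_value`, `unstable` (count columns are `NA` for continuous predictors).
#' @export
fit_univariate <- function(outcome, predictor, feature = "x",
                           reference = NULL) {
  stopifnot(all(outcome %in% c(0, 1)))
  if (length(unique(outcome)) < 2) {
    stop_bad_arg("both outcome classes must be present")
  }
  keep <- !is.na(predictor)
  y <- outcome[keep]; x <- predictor[keep]

  if (is.numeric(x)) {
    fit <- glm(y ~ x, family = binomial(),
               control = glm.control(epsilon = 1e-12, maxit = 100))
    est <- summary(fit)$coefficients["x", ]
    return(data.frame(
      feature = feature, level = NA_character_,
      n_ref_without = NA_integer_, n_ref_with = NA_integer_,
      n_without = NA_integer_, n_with = NA_integer_,
      odds_ratio = exp(est["Estimate"]),
      ci_low = exp(est["Estimate"] - qnorm(0.975) * est["Std. Error"]),
      ci_high = exp(est["Estimate"] + qnorm(0.975) * est["Std. Error"]),
      p_value = est["Pr(>|z|)"], unstable = FALSE,
      row.names = NULL, stringsAsFactors = FALSE))
  }

  x <- as.character(x)
  levs <- sort(unique(x))
  reference <- reference %||% levs[1]
  if (!reference %in% levs) stop_bad_arg("reference level absent: ", reference)
  f <- factor(x, levels = c(reference, setdiff(levs, reference)))
  fit <- glm(y ~ f, family = binomial(),
             control = glm.control(epsilon = 1e-12, maxit = 100))
  cf <- summary(fit)$coefficients
  tab <- table(factor(y, levels = 0:1), f)
  out <- lapply(setdiff(levels(f), reference), function(lv) {
    rn <- paste0("f", lv)
    est <- cf[rn, ]
    cells <- c(tab["0", reference], tab["1", reference],
               tab["0", lv], tab["1", lv])
    data.frame(
      feature = feature, level = lv,
      n_ref_without = cells[1], n_ref_with = cells[2],
      n_without = cells[3], n_with = cells[4],
      odds_ratio = exp(est["Estimate"]),
      ci_low = exp(est["Estimate"] - qnorm(0.975) * est["Std. Error"]),
      ci_high = exp(est["Estimate"] + qnorm(0.975) * est["Std. Error"]),
      p_value = est["Pr(>|z|)"],
      unstable = any(cells == 0),
      row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Odds ratio from 2x2 counts
#'
#' Convenience wrapper reconstructing the patient-level vectors from a printed
#' 2x2 table (`reference` vs `level` rows, each split into patients without /
#' with the event) and fitting the univariate logistic model.
#'
#' @param ref_without,ref_with Counts in the reference level without / with
#'   the event.
#' @param lvl_without,lvl_with Counts in the contrast level without / with
#'   the event.
#' @return One-row data.frame as [fit_univariate()].
#' @export
or_from_counts <- function(ref_without, ref_with, lvl_without, lvl_with) {
  counts <- c(ref_without, ref_with, lvl_without, lvl_with)
  stopifnot(all(counts >= 0), sum(counts) > 0)
  y <- rep(c(0L, 1L, 0L, 1L), counts)
  x <- rep(c("ref", "ref", "level", "level"), counts)
  fit_univariate(y, x, feature = "counts", reference = "ref")
}

#' Bonferroni adjustment
#'
#' `p_adjusted = min(1, p * m)`; order-preserving. `m` defaults to the number
#' of p-values supplied but may be set to the number of tests performed in the
#' run when adjusting a subset.
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @param m Number of tests (>= 1).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop_bad_arg("p-values must lie in [0, 1]")
  }
  stopifnot(is_scalar_number(m), m >= 1)
  pmin(1, p_values * m)
}

#' Univariate odds-ratio screen over a cohort
#'
#' Fits one univariate logistic regression per feature in the schema
#' (one odds-ratio row per non-reference level for categoricals, one per-unit
#' row for continuous features) and Bonferroni-adjusts the Wald p-values with
#' `m` equal to the number of odds-ratio rows actually computed, which is
#' recorded in the result.
#'
#' @param data Cohort data.frame or `ril_cohort`.
#' @param schema `ril_schema` (taken from the cohort when omitted).
#' @param outcome Outcome column name (default `"lymphopenia"`).
#' @return Data.frame of class `ril_univariate_screen` with one row per test
#'   and columns as [fit_univariate()] plus `p_adjusted`; the number of tests
#'   is attached as attribute `m`.
#' @export
screen_univariate <- function(data, schema = NULL, outcome = "lymphopenia") {
  if (inherits(data, "ril_cohort")) {
    schema <- schema %||% data$schema
    data <- data$data
  }
  stopifnot(is.data.frame(data), is.data.frame(schema))
  y <- data[[outcome]]
  rows <- lapply(seq_len(nrow(schema)), function(i) {
    nm <- schema$name[i]
    ref <- if (schema$kind[i] == "categorical") schema$reference[i] else NULL
    fit_univariate(y, data[[nm]], feature = nm, reference = ref)
  })
  out <- do.call(rbind, rows)
  m <- nrow(out)
  out$p_adjusted <- bonferroni(out$p_value, m)
  attr(out, "m") <- m
  class(out) <- c("ril_univariate_screen", "data.frame")
  out
}
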