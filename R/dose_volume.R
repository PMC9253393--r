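#' Assemble dose-volume attribution points
#'
#' Joins the dose-metric catalog with an attribution summary: one point per
#' dosimetric metric carrying its representative irradiation dose (Gy),
#' irradiated volume, mean |SHAP| and direction score. A warning is emitted
#' when the catalog mixes volume units (percent organ volume vs absolute
#' volume), since the log-volume regression then pools heterogeneous scales.
#'
#' @param catalog Data.frame as [generate_dose_catalog()] (columns `metric`,
#'   `dose_gy`, `volume`, optionally `volume_unit`).
#' @param summary A `ril_attribution_summary`.
#' @return Data.frame with `metric`, `dose_gy`, `volume`, `mean_abs_shap`,
#'   `direction`.
#' @export
dose_volume_points <- function(catalog, summary) {
  stopifnot(all(c("metric", "dose_gy", "volume") %in% names(catalog)))
  if ("volume_unit" %in% names(catalog) &&
      length(unique(catalog$volume_unit)) > 1) {
    warning("catalog mixes volume units; log-volume regression pools them",
            call. = FALSE)
  }
  idx <- match(catalog$metric, summary$feature)
  if (anyNA(idx)) {
    stop_bad_arg("metrics missing from attribution summary: ",
                 paste(catalog$metric[is.na(idx)], collapse = ", "))
  }
  data.frame(metric = catalog$metric, dose_gy = catalog$dose_gy,
             volume = catalog$volume,
             mean_abs_shap = summary$mean_abs_shap[idx],
             direction = summary$direction[idx], stringsAsFactors = FALSE)
}

ols_on_attribution <- function(response, shap, label) {
  if (length(response) < 3) {
    stop_bad_arg("need at least 3 points for the ", label, " regression")
  }
  fit <- lm(response ~ shap)
  cf <- summary(fit)$coefficients
  list(slope = unname(cf["shap", "Estimate"]),
       intercept = unname(cf["(Intercept)", "Estimate"]),
       slope_se = unname(cf["shap", "Std. Error"]),
       p_value = unname(cf["shap", "Pr(>|t|)"]),
       n = length(response))
}

#' Regress log10 irradiated volume on attribution importance
#'
#' Ordinary least squares of `log10(volume)` on mean |SHAP| across dosimetric
#' metrics: a positive slope means the more lymphotoxic metrics are those
#' irradiating larger volumes.
#'
#' @param points Data.frame from [dose_volume_points()] (needs `volume` > 0
#'   and `mean_abs_shap`).
#' @return List with `slope`, `intercept`, `slope_se`, `p_value`, `n`.
#' @export
regress_volume_on_attribution <- function(points) {
  stopifnot(all(points$volume > 0))
  ols_on_attribution(log10(points$volume), points$mean_abs_shap, "volume")
}

#' Regress log2 irradiation dose on attribution importance
#'
#' Ordinary least squares of `log2(dose)` on mean |SHAP| across dosimetric
#' metrics.
#'
#' @param points Data.frame from [dose_volume_points()] (needs `dose_gy` > 0).
#' @return List with `slope`, `intercept`, `slope_se`, `p_value`, `n`.
#' @export
regress_dose_on_attribution <- function(points) {
  stopifnot(all(points$dose_gy > 0))
  ols_on_attribution(log2(points$dose_gy), points$mean_abs_shap, "dose")
}

#' Per-metric volume-dose correlation profile
#'
#' For each dosimetric metric, the Pearson correlation between per-patient
#' irradiated volume and irradiation dose. Metrics with a negative correlation
#' are flagged heart-like (their irradiated volume shrinks as their dose
#' grows) and are the ones to exclude from monotone volume-dose claims;
#' constant vectors yield an undefined, flagged correlation.
#'
#' @param dvh Long data.frame with columns `metric`, `dose_gy`, `volume` (one
#'   row per patient and metric), at least 2 patients per metric.
#' @return Data.frame with `metric`, `correlation`, `negative_link` and
#'   `degenerate` flags.
#' @export
volume_dose_profile <- function(dvh) {
  stopifnot(all(c("metric", "dose_gy", "volume") %in% names(dvh)))
  out <- lapply(unique(dvh$metric), function(mname) {
    sub <- dvh[dvh$metric == mname, ]
    if (nrow(sub) < 2) stop_bad_arg("metric ", mname, " has fewer than 2 patients")
    degenerate <- sd(sub$dose_gy) == 0 || sd(sub$volume) == 0
    r <- if (degenerate) NA_real_ else cor(sub$dose_gy, sub$volume)
    data.frame(metric = mname, correlation = r,
               negative_link = !degenerate && r < 0,
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Full dose-volume attribution report
#'
#' Runs both attribution regressions and the per-metric volume-dose profile,
#' and restates only what is literally computed: slopes, their standard
#' errors and p-values, and which metrics carry a negative volume-dose link.
#'
#' @param catalog Dose-metric catalog.
#' @param summary A `ril_attribution_summary`.
#' @param dvh Optional long per-patient DVH table for the volume-dose profile.
#' @return List with `points`, `volume_regression`, `dose_regression` and
#'   (when `dvh` is supplied) `profile`.
#' @export
dose_volume_report <- function(catalog, summary, dvh = NULL) {
  points <- dose_volume_points(catalog, summary)
  out <- list(points = points,
              volume_regression = regress_volume_on_attribution(points),
              dose_regression = regress_dose_on_attribution(points))
  if (!is.null(dvh)) out$profile <- volume_dose_profile(dvh)
  out
}
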