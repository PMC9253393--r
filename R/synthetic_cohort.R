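#' Default dose-metric specification
#'
#' Nine dosimetric summary features of a breast radiotherapy plan, each with a
#' representative irradiation dose (Gy) and corresponding irradiated volume
#' (percent organ volume for Vx / mean-dose metrics, litres for the whole-body
#' integral dose surrogate) and the sign of the link between irradiated volume
#' and the latent irradiation extent. The mean heart dose is the one metric
#' with a negative volume link: in tangential breast plans a higher mean heart
#' dose accompanies a smaller irradiated range.
#'
#' @return A data.frame with columns `name`, `dose_gy`, `volume`,
#'   `volume_link_sign` (+1 or -1) and `volume_unit`.
#' @export
default_dose_metric_spec <- function() {
  data.frame(
    name = c(
      "integral_body_dose", "mean_heart_dose", "max_heart_dose",
      "v20_ipsilateral_lung", "v5_ipsilateral_lung",
      "mean_ipsilateral_lung_dose", "v20_bilateral_lungs",
      "v5_bilateral_lungs", "mean_bilateral_lungs_dose"
    ),
    dose_gy = c(4.0, 2.1, 40.0, 20, 5, 10.5, 20, 5, 5.3),
    volume  = c(16, 6, 0.05, 21, 39, 30, 10, 20, 15),
    volume_link_sign = c(1, -1, 1, 1, 1, 1, 1, 1, 1),
    volume_unit = c("L", "%", "%", "%", "%", "%", "%", "%", "%"),
    stringsAsFactors = FALSE
  )
}

#' Default blood-count distribution parameters
#'
#' Lognormal log-mean/log-sd per baseline analyte, moment-matched (via
#' [lognormal_params_from_quartiles()]) to published cohort medians and
#' quartiles. Counts are in 10^9/L except hemoglobin (g/L).
#'
#' @return Named list of `list(meanlog, sdlog)` per analyte feature.
#' @export
default_blood_count_params <- function() {
  q <- list(
    baseline_wbc        = c(5.3, 4.3, 6.4),
    baseline_hemoglobin = c(119, 110, 126),
    baseline_platelet   = c(234, 196, 276),
    baseline_neutrophil = c(3.2, 2.4, 4.2),
    baseline_lymphocyte = c(1.53, 1.20, 1.86),
    baseline_monocyte   = c(0.31, 0.24, 0.39)
  )
  lapply(q, function(v) lognormal_params_from_quartiles(v[1], v[2], v[3]))
}

# Categorical features: levels, marginal proportions and reference level.
# Proportions are the pooled cohort marginals of the published Table-1 layout;
# joint dependencies between categoricals are deliberately not modelled.
default_categorical_spec <- function() {
  list(
    family_history   = list(group = "clinical", levels = c("without", "with"),
                            probs = c(0.654, 0.346)),
    smoking_history  = list(group = "clinical",
                            levels = c("without", "with", "unknown"),
                            probs = c(0.734, 0.005, 0.261)),
    drinking_history = list(group = "clinical",
                            levels = c("without", "with", "unknown"),
                            probs = c(0.734, 0.005, 0.261)),
    menopausal       = list(group = "clinical",
                            levels = c("premenopausal", "perimenopausal",
                                       "postmenopausal"),
                            probs = c(0.671, 0.066, 0.263)),
    modified_n_stage = list(group = "tumor", levels = c("0", "more_than_0"),
                            probs = c(0.380, 0.620)),
    modified_stage   = list(group = "tumor", levels = c("I", "II", "III"),
                            probs = c(0.256, 0.452, 0.292)),
    tumor_side       = list(group = "tumor", levels = c("left", "right"),
                            probs = c(0.506, 0.494)),
    er               = list(group = "tumor", levels = c("negative", "positive"),
                            probs = c(0.277, 0.723)),
    pr               = list(group = "tumor", levels = c("negative", "positive"),
                            probs = c(0.362, 0.638)),
    her2             = list(group = "tumor", levels = c("negative", "positive"),
                            probs = c(0.739, 0.261)),
    ihc              = list(group = "tumor",
                            levels = c("HR+/HER2-", "HR-/HER2+", "HR+/HER2+",
                                       "HR-/HER2-"),
                            probs = c(0.587, 0.109, 0.154, 0.149)),
    rt_technique     = list(group = "radiotherapy",
                            levels = c("RapidArc", "2D-fields", "3D-fields"),
                            probs = c(0.170, 0.358, 0.472)),
    rt_fields        = list(group = "radiotherapy",
                            levels = c("tangential_breast_only",
                                       "regional_lymphatics"),
                            probs = c(0.362, 0.638)),
    rt_dose          = list(group = "radiotherapy",
                            levels = c("40.5Gy_15fx", "more_than_50Gy_25fx"),
                            probs = c(0.901, 0.099)),
    electron_boost   = list(group = "radiotherapy",
                            levels = c("none", "10Gy_5fx", "16Gy_8fx"),
                            probs = c(0.489, 0.452, 0.059)),
    surgery_regimen  = list(group = "treatment", levels = c("BCT", "MRM"),
                            probs = c(0.486, 0.514)),
    axillary_surgery = list(group = "treatment", levels = c("SLNB", "ALND"),
                            probs = c(0.346, 0.654)),
    margin           = list(group = "treatment",
                            levels = c("clear", "close_or_positive"),
                            probs = c(0.952, 0.048)),
    chemo_strategy   = list(group = "treatment",
                            levels = c("none", "neoadjuvant", "adjuvant",
                                       "neoadjuvant_adjuvant"),
                            probs = c(0.098, 0.177, 0.701, 0.024)),
    chemo_regimen    = list(group = "treatment",
                            levels = c("others", "taxane",
                                       "anthracycline_taxane"),
                            probs = c(0.124, 0.243, 0.633)),
    anti_her2_therapy = list(group = "treatment", levels = c("without", "with"),
                             probs = c(0.750, 0.250)),
    endocrine_therapy = list(group = "treatment", levels = c("without", "with"),
                             probs = c(0.258, 0.742))
  )
}

#' Default planted effect vector
#'
#' Signed log-odds effects per standardised unit used by the default generator
#' configuration: a strongly protective baseline lymphocyte count, a promoting
#' whole-body integral dose and bilateral-lung low-dose bath, and a moderately
#' protective baseline platelet count. All other features are null.
#'
#' @return Named numeric vector of log-odds effects.
#' @export
default_effect_vector <- function() {
  c(baseline_lymphocyte = -1.2,
    integral_body_dose  = 1.0,
    v5_bilateral_lungs  = 0.6,
    baseline_platelet   = -0.5)
}

#' Build a generator configuration
#'
#' Assembles and validates the configuration for [generate_cohort()]. Defaults
#' emulate the published Testing cohort: 589 patients, a 57.7% lymphopenia
#' rate, nine multicollinear dosimetric metrics sharing a latent irradiation
#' extent, lognormal baseline blood counts and Table-1-style categorical
#' marginals.
#'
#' @param n_patients Number of patients (default 589).
#' @param event_rate_target Target lymphopenia prevalence in (0, 1)
#'   (default 0.577).
#' @param effect_vector Named numeric vector of signed log-odds effects per
#'   standardised unit; names are continuous feature names or
#'   `"feature:level"` indicators. Default [default_effect_vector()].
#' @param dose_metric_spec Data.frame as returned by
#'   [default_dose_metric_spec()].
#' @param blood_count_params Named list of lognormal parameters per analyte.
#' @param missingness_rate MCAR missingness fraction on continuous features,
#'   in `[0, 1)` (default 0.02).
#' @param seed Integer seed.
#' @param dose_loading,dose_noise_sd Log-scale loading of dosimetric features
#'   on the latent irradiation extent and the idiosyncratic log-noise; the
#'   defaults (0.4, 0.3) imply pairwise dose-metric correlations around 0.6,
#'   comfortably above the 0.18 floor the analysis assumes.
#' @param volume_loading,volume_noise_sd Same for per-patient irradiated
#'   volumes (signed per metric by `volume_link_sign`).
#' @param lln Lower limit of normal for the lymphocyte count, per microlitre
#'   (default 1000).
#' @param dose_cor_floor Documented minimum pairwise dose-metric correlation
#'   the generated cohorts are expected to exceed (default 0.18).
#' @return Object of class `ril_generator_config`.
#' @export
generator_config <- function(n_patients = 589,
                             event_rate_target = 0.577,
                             effect_vector = default_effect_vector(),
                             dose_metric_spec = default_dose_metric_spec(),
                             blood_count_params = default_blood_count_params(),
                             missingness_rate = 0.02,
                             seed = 1L,
                             dose_loading = 0.4,
                             dose_noise_sd = 0.3,
                             volume_loading = 0.45,
                             volume_noise_sd = 0.25,
                             lln = 1000,
                             dose_cor_floor = 0.18) {
  stopifnot(is_scalar_number(n_patients), n_patients >= 1)
  if (!is_scalar_number(event_rate_target) ||
      event_rate_target <= 0 || event_rate_target >= 1) {
    stop_bad_arg("event_rate_target must lie strictly between 0 and 1")
  }
  if (length(effect_vector) &&
      (is.null(names(effect_vector)) || any(!is.finite(effect_vector)))) {
    stop_bad_arg("effect_vector entries must be finite and named")
  }
  stopifnot(is.data.frame(dose_metric_spec),
            all(c("name", "dose_gy", "volume", "volume_link_sign") %in%
                  names(dose_metric_spec)))
  if (anyDuplicated(dose_metric_spec$name)) {
    stop_bad_arg("duplicate dose metric names: ",
                 paste(unique(dose_metric_spec$name[
                   duplicated(dose_metric_spec$name)]), collapse = ", "))
  }
  if (any(dose_metric_spec$dose_gy <= 0) || any(dose_metric_spec$volume <= 0)) {
    stop_bad_arg("dose_gy and volume must be positive")
  }
  stopifnot(all(dose_metric_spec$volume_link_sign %in% c(-1, 1)))
  if (!is_scalar_number(missingness_rate) || missingness_rate < 0 ||
      missingness_rate >= 1) {
    stop_bad_arg("missingness_rate must lie in [0, 1)")
  }
  structure(list(
    n_patients = as.integer(n_patients),
    event_rate_target = event_rate_target,
    effect_vector = effect_vector,
    dose_metric_spec = dose_metric_spec,
    blood_count_params = blood_count_params,
    missingness_rate = missingness_rate,
    seed = as.integer(seed),
    dose_loading = dose_loading, dose_noise_sd = dose_noise_sd,
    volume_loading = volume_loading, volume_noise_sd = volume_noise_sd,
    lln = lln, dose_cor_floor = dose_cor_floor
  ), class = "ril_generator_config")
}

#' Feature schema of the synthetic cohort
#'
#' One row per feature: name, feature group (clinical, tumor, blood,
#' radiotherapy, treatment), kind (continuous or categorical), pipe-separated
#' category levels with the first level as reference, and units.
#'
#' @param config A `ril_generator_config`.
#' @return A data.frame of class `ril_schema`.
#' @export
synthetic_schema <- function(config = generator_config()) {
  cont <- data.frame(
    name = c("age", "tumor_size", "ki67",
             names(config$blood_count_params),
             config$dose_metric_spec$name),
    group = c("clinical", "tumor", "tumor",
              rep("blood", length(config$blood_count_params)),
              rep("radiotherapy", nrow(config$dose_metric_spec))),
    kind = "continuous", levels = NA_character_, reference = NA_character_,
    units = c("years", "cm", "%",
              "10^9/L", "g/L", "10^9/L", "10^9/L", "10^9/L", "10^9/L",
              ifelse(config$dose_metric_spec$name %in%
                       c("v20_ipsilateral_lung", "v5_ipsilateral_lung",
                         "v20_bilateral_lungs", "v5_bilateral_lungs"),
                     "%", "Gy")),
    stringsAsFactors = FALSE
  )
  cats <- default_categorical_spec()
  cat_df <- data.frame(
    name = names(cats),
    group = vapply(cats, `[[`, "", "group"),
    kind = "categorical",
    levels = vapply(cats, function(s) paste(s$levels, collapse = "|"), ""),
    reference = vapply(cats, function(s) s$levels[1], ""),
    units = NA_character_, stringsAsFactors = FALSE
  )
  out <- rbind(cont, cat_df)
  rownames(out) <- NULL
  class(out) <- c("ril_schema", "data.frame")
  out
}

schema_levels <- function(schema, feature) {
  lv <- schema$levels[schema$name == feature]
  if (!length(lv) || is.na(lv)) return(character())
  strsplit(lv, "|", fixed = TRUE)[[1]]
}

# Bisection on the intercept of the logistic model so the mean response hits
# the target event rate; derivative-free and deterministic.
calibrate_intercept <- function(lp, target, tol = 1e-4) {
  f <- function(b) mean(plogis(b + lp)) - target
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0) {
    stop_bad_arg("event_rate_target unattainable: intercept calibration failed")
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol) return(mid)
    if (fm > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Truncated-lognormal draw for the post-RT lymphocyte count so the count is
# consistent with the drawn binary outcome at the configured LLN.
draw_post_counts <- function(event, lln, meanlog, sdlog) {
  p_below <- plnorm_safe(lln, meanlog, sdlog)
  u <- runif(length(event))
  u <- ifelse(event == 1L, u * p_below, p_below + u * (1 - p_below))
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  qlnorm(u, meanlog, sdlog)
}

plnorm_safe <- function(q, meanlog, sdlog) {
  stats::plnorm(q, meanlog = meanlog, sdlog = sdlog)
}

#' Generate a synthetic cohort
#'
#' Draws a tabular cohort with five feature groups, per-patient dose-volume
#' summaries, a dose-metric catalog and the ground truth of the generating
#' model. Dosimetric features are monotone functions of a shared latent
#' irradiation extent plus lognormal noise, giving all pairwise dose-metric
#' correlations above the configured floor; the mean heart dose has a negative
#' volume-extent link. The binary lymphopenia outcome is drawn from a logistic
#' model on standardised features with the configured effect vector, intercept
#' calibrated by bisection to the target event rate. Missingness is injected
#' completely at random on continuous features only.
#'
#' @param config A [generator_config()].
#' @return Object of class `ril_cohort`: list with `data` (data.frame with
#'   `patient_id`, the features, `pre_rt_lymphocytes`, `post_rt_lymphocytes`
#'   per microlitre and the binary `lymphopenia` outcome), `schema`, `dvh`
#'   (long per-patient, per-metric dose and irradiated volume), `catalog`
#'   (as [generate_dose_catalog()]) and `truth` (effect vector, per-patient
#'   linear predictor, calibrated intercept, realised event rate).
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "ril_generator_config"))
  set.seed(config$seed)
  n <- config$n_patients
  schema <- synthetic_schema(config)

  # latent irradiation extent shared by all dosimetric features
  z <- rnorm(n)

  dat <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                    stringsAsFactors = FALSE)
  dat$age <- round(pmax(18, rnorm(n, 45, 8.9)))
  dat$tumor_size <- rlnorm(n, log(2), log(2.8 / 1.3) / (2 * qnorm(0.75)))
  dat$ki67 <- rlnorm(n, log(30), log(40 / 15) / (2 * qnorm(0.75)))
  for (analyte in names(config$blood_count_params)) {
    p <- config$blood_count_params[[analyte]]
    dat[[analyte]] <- rlnorm(n, p$meanlog, p$sdlog)
  }

  spec <- config$dose_metric_spec
  dvh <- vector("list", nrow(spec))
  for (j in seq_len(nrow(spec))) {
    dose_j <- spec$dose_gy[j] *
      exp(config$dose_loading * z + rnorm(n, 0, config$dose_noise_sd))
    vol_j <- spec$volume[j] *
      exp(spec$volume_link_sign[j] * config$volume_loading * z +
            rnorm(n, 0, config$volume_noise_sd))
    dat[[spec$name[j]]] <- dose_j
    dvh[[j]] <- data.frame(metric = spec$name[j], patient_id = dat$patient_id,
                           dose_gy = dose_j, volume = vol_j,
                           stringsAsFactors = FALSE)
  }
  dvh <- do.call(rbind, dvh)

  cats <- default_categorical_spec()
  for (nm in names(cats)) {
    s <- cats[[nm]]
    dat[[nm]] <- sample(s$levels, n, replace = TRUE, prob = s$probs)
  }

  # linear predictor on standardised features / centred indicators
  lp <- rep(0, n)
  for (nm in names(config$effect_vector)) {
    beta <- config$effect_vector[[nm]]
    if (beta == 0) next
    if (grepl(":", nm, fixed = TRUE)) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      if (!parts[1] %in% names(dat) ||
          !parts[2] %in% schema_levels(schema, parts[1])) {
        stop_bad_arg("effect_vector names unknown feature or level: ", nm)
      }
      x <- as.numeric(dat[[parts[1]]] == parts[2])
      lp <- lp + beta * (x - mean(x))
    } else {
      if (!nm %in% names(dat) || !is.numeric(dat[[nm]])) {
        stop_bad_arg("effect_vector names unknown continuous feature: ", nm)
      }
      lp <- lp + beta * as.numeric(scale(dat[[nm]]))
    }
  }

  intercept <- calibrate_intercept(lp, config$event_rate_target)
  event <- rbinom(n, 1L, plogis(intercept + lp))

  dat$pre_rt_lymphocytes <- dat$baseline_lymphocyte * 1000
  post_par <- lognormal_params_from_quartiles(950, 750, 1170)
  dat$post_rt_lymphocytes <- draw_post_counts(event, config$lln,
                                              post_par$meanlog,
                                              post_par$sdlog)
  dat$lymphopenia <- event

  if (config$missingness_rate > 0) {
    cont <- schema$name[schema$kind == "continuous"]
    for (nm in cont) {
      miss <- runif(n) < config$missingness_rate
      dat[[nm]][miss] <- NA
    }
  }

  truth <- structure(list(effect_vector = config$effect_vector,
                          linear_predictor = lp, intercept = intercept,
                          event_rate = mean(event)),
                     class = "ril_ground_truth")
  structure(list(data = dat, schema = schema, dvh = dvh,
                 catalog = generate_dose_catalog(config), truth = truth,
                 config = config),
            class = "ril_cohort")
}

#' Generate the dose-metric catalog
#'
#' Per dosimetric feature, the representative (dose, volume) pair extracted
#' from DVH summaries: the catalog passes through the configured
#' representative values. Duplicate metric names are rejected.
#'
#' @param config A [generator_config()].
#' @return Data.frame with `metric`, `dose_gy`, `volume`, `volume_unit`,
#'   `volume_link_sign`.
#' @export
generate_dose_catalog <- function(config = generator_config()) {
  stopifnot(inherits(config, "ril_generator_config"))
  spec <- config$dose_metric_spec
  if (!nrow(spec)) stop_bad_arg("dose_metric_spec must be non-empty")
  if (anyDuplicated(spec$name)) {
    stop_bad_arg("duplicate dose metric names in dose_metric_spec")
  }
  data.frame(metric = spec$name, dose_gy = spec$dose_gy, volume = spec$volume,
             volume_unit = spec$volume_unit %||% NA_character_,
             volume_link_sign = spec$volume_link_sign,
             stringsAsFactors = FALSE)
}

#' @export
print.ril_cohort <- function(x, ...) {
  cat(sprintf(
    "<ril_cohort> %d patients, %d features, event rate %.3f (target %.3f)\n",
    nrow(x$data), nrow(x$schema), x$truth$event_rate,
    x$config$event_rate_target))
  invisible(x)
}

#' Write cohort, catalog and ground truth to disk
#'
#' The cohort is written as CSV (one row per patient, header = feature names,
#' missing = empty cell), the catalog as CSV and the ground truth as JSON.
#'
#' @param cohort A `ril_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ril_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cohort = file.path(dir, "cohort.csv"),
             catalog = file.path(dir, "dose_catalog.csv"),
             dvh = file.path(dir, "dvh_summaries.csv"),
             truth = file.path(dir, "ground_truth.json"))
  write.csv(cohort$data, paths["cohort"], row.names = FALSE, na = "")
  write.csv(cohort$catalog, paths["catalog"], row.names = FALSE)
  write.csv(cohort$dvh, paths["dvh"], row.names = FALSE)
  jsonlite::write_json(
    list(effect_vector = as.list(cohort$truth$effect_vector),
         intercept = cohort$truth$intercept,
         event_rate = cohort$truth$event_rate,
         seed = cohort$config$seed),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
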