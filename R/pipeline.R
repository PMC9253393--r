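#' Read or write a feature schema as YAML or JSON
#'
#' The schema config holds one entry per feature: group, kind, category
#' levels (first level = reference) and units. Format is inferred from the
#' file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param path File path.
#' @return A `ril_schema` data.frame.
#' @export
read_schema <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  rows <- lapply(names(raw), function(nm) {
    e <- raw[[nm]]
    data.frame(name = nm, group = e$group, kind = e$kind,
               levels = if (is.null(e$levels)) NA_character_ else
                 paste(unlist(e$levels), collapse = "|"),
               reference = if (is.null(e$levels)) NA_character_ else
                 unlist(e$levels)[1],
               units = e$units %||% NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ril_schema", "data.frame")
  out
}

#' @rdname read_schema
#' @param schema A `ril_schema`.
#' @export
write_schema <- function(schema, path) {
  entries <- lapply(seq_len(nrow(schema)), function(i) {
    e <- list(group = schema$group[i], kind = schema$kind[i])
    if (!is.na(schema$levels[i])) e$levels <- schema_levels(schema, schema$name[i])
    if (!is.na(schema$units[i])) e$units <- schema$units[i]
    e
  })
  names(entries) <- schema$name
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(entries, path)
  else jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pipeline run configuration
#'
#' @param out_dir Output directory.
#' @param seed Base integer seed; every stage derives its own seed from it.
#' @param B Number of resampling iterations (default 100).
#' @param generator A [generator_config()] used when no cohort CSV is given
#'   (its seed is overridden by the run seed).
#' @param cohort_csv,schema_path Optional external cohort CSV and schema
#'   (YAML/JSON) instead of simulation.
#' @param catalog_csv Optional external dose-metric catalog CSV; when neither
#'   a catalog file nor a simulated catalog is available the dose-volume stage
#'   is skipped with a notice.
#' @param grid_mode `"fast"` (shipped default configuration), `"random"`
#'   (randomized search of `grid_size` configurations per iteration) or
#'   `"full"` (exhaustive grid).
#' @param grid_size Randomized-search budget (default 200).
#' @param lln Lower limit of normal for grading, per microlitre.
#' @param pairing_threshold Discrepancy threshold for matched pairs.
#' @param attribution_mode `"feature"` (default: attributions correlated with
#'   the feature's own values, recovering protective signs) or `"outcome"`
#'   (attributions correlated with outcomes; non-negative by construction).
#' @param threshold Classification threshold.
#' @param nrounds Boosting rounds.
#' @param probes Probe features for the matched-pair stage (default: the
#'   heart and ipsilateral-lung V20 metrics present in the data).
#' @param group_models Also fit the five per-group models (default `TRUE`).
#' @return Object of class `ril_run_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, B = 100,
                            generator = generator_config(),
                            cohort_csv = NULL, schema_path = NULL,
                            catalog_csv = NULL,
                            grid_mode = c("fast", "random", "full"),
                            grid_size = 200, lln = 1000,
                            pairing_threshold = 0.10,
                            attribution_mode = c("feature", "outcome"),
                            threshold = 0.5, nrounds = 200, probes = NULL,
                            group_models = TRUE) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), B = B,
                 generator = generator, cohort_csv = cohort_csv,
                 schema_path = schema_path, catalog_csv = catalog_csv,
                 grid_mode = match.arg(grid_mode), grid_size = grid_size,
                 lln = lln, pairing_threshold = pairing_threshold,
                 attribution_mode = match.arg(attribution_mode),
                 threshold = threshold, nrounds = nrounds, probes = probes,
                 group_models = group_models),
            class = "ril_run_config")
}

pipeline_log <- function(state, ...) {
  line <- paste0(...)
  cat(line, "\n", sep = "", file = state$log_path, append = TRUE)
  message(line)
}

run_stage <- function(state, stage, expr) {
  pipeline_log(state, "[stage ", stage, "] start")
  out <- tryCatch(expr, error = function(e) {
    pipeline_log(state, "[stage ", stage, "] FAILED: ", conditionMessage(e))
    stop("pipeline aborted in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  pipeline_log(state, "[stage ", stage, "] done")
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate -> preprocess -> screen -> model -> attribute ->
#' dose-volume -> match as one configured run. Every inter-stage data product
#' flows through files in the output directory; all artifacts are reproducible
#' from the run seed, and the seed plus a hash of the configuration are
#' recorded in `run_info.json`. A stage failure aborts the run naming the
#' stage, leaving the log and earlier artifacts in place.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of the main in-memory results (`cohort`,
#'   `screen`, `fit` or `group_fits`, `attribution`, `dose_volume`, `pairs`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ril_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list(log_path = file.path(config$out_dir, "pipeline.log"))
  cat("", file = state$log_path)   # truncate

  config_path <- file.path(config$out_dir, "config.json")
  cfg_export <- config
  cfg_export$generator <- unclass(cfg_export$generator)
  cfg_export$generator$dose_metric_spec <- NULL
  jsonlite::write_json(unclass(cfg_export), config_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE, null = "null")
  config_hash <- unname(tools::md5sum(config_path))

  # -- simulate / load ------------------------------------------------------
  cohort <- run_stage(state, "simulate", {
    if (is.null(config$cohort_csv)) {
      gen <- config$generator
      gen$seed <- derive_seed(config$seed, 1L)
      gen$lln <- config$lln
      sim <- generate_cohort(gen)
      write_cohort(sim, config$out_dir)
      sim
    } else {
      schema <- if (is.null(config$schema_path)) synthetic_schema()
                else read_schema(config$schema_path)
      dat <- read.csv(config$cohort_csv, stringsAsFactors = FALSE)
      catalog <- if (!is.null(config$catalog_csv)) {
        read.csv(config$catalog_csv, stringsAsFactors = FALSE)
      }
      structure(list(data = dat, schema = schema, dvh = NULL,
                     catalog = catalog, truth = NULL, config = NULL),
                class = "ril_cohort")
    }
  })

  # -- preprocess -----------------------------------------------------------
  mm <- run_stage(state, "preprocess", {
    dat <- cohort$data
    if ("post_rt_lymphocytes" %in% names(dat)) {
      dat$lymphopenia_grade <- grade_lymphopenia(dat$post_rt_lymphocytes,
                                                 config$lln)
      dat$lymphopenia <- as.integer(dat$lymphopenia_grade >= 1)
      cohort$data <- dat
    }
    encode_cohort(dat, cohort$schema)
  })

  # -- univariate screen ----------------------------------------------------
  screen <- run_stage(state, "screen", {
    s <- screen_univariate(cohort$data, cohort$schema)
    out <- cbind(s, m_tests = attr(s, "m"))
    write.csv(out, file.path(config$out_dir, "univariate_screen.csv"),
              row.names = FALSE)
    s
  })

  # -- modeling -------------------------------------------------------------
  grid <- switch(config$grid_mode,
                 fast = NULL,
                 random = hyper_grid_sample(config$grid_size,
                                            seed = derive_seed(config$seed, 3L)),
                 full = expand.grid(hyper_grid()))
  plans <- make_plans(nrow(mm$x), B = config$B,
                      seed = derive_seed(config$seed, 2L),
                      outcome = mm$outcome)
  trained <- run_stage(state, "train", {
    if (config$group_models) {
      res <- run_group_models(mm, plans, grid = grid,
                              nrounds = config$nrounds,
                              threshold = config$threshold)
      write.csv(res$summary,
                file.path(config$out_dir, "metrics_summary.csv"),
                row.names = FALSE)
      write.csv(res$fits$full$metrics,
                file.path(config$out_dir, "metrics_iterations.csv"),
                row.names = FALSE)
      res
    } else {
      fit <- run_bootstrap_models(mm, plans, grid = grid,
                                  nrounds = config$nrounds,
                                  threshold = config$threshold)
      write.csv(cbind(group = "full", summarize_metrics(fit)),
                file.path(config$out_dir, "metrics_summary.csv"),
                row.names = FALSE)
      write.csv(fit$metrics,
                file.path(config$out_dir, "metrics_iterations.csv"),
                row.names = FALSE)
      list(fits = list(full = fit))
    }
  })
  fit <- trained$fits$full

  # -- attribution ----------------------------------------------------------
  summary_tab <- run_stage(state, "attribute", {
    s <- attribution_summary(fit, mode = config$attribution_mode)
    write.csv(s, file.path(config$out_dir, "attribution_summary.csv"),
              row.names = FALSE)
    groups <- setNames(mm$columns$group, mm$columns$column)
    export_attribution_graph(s, groups = groups,
                             path = file.path(config$out_dir,
                                              "attribution_graph.graphml"))
    s
  })

  # -- dose-volume ----------------------------------------------------------
  dosevol <- run_stage(state, "dosevol", {
    if (is.null(cohort$catalog)) {
      pipeline_log(state, "[stage dosevol] no dose catalog; stage skipped")
      NULL
    } else {
      rep <- dose_volume_report(cohort$catalog, summary_tab, dvh = cohort$dvh)
      write.csv(rep$points,
                file.path(config$out_dir, "dose_volume_points.csv"),
                row.names = FALSE)
      jsonlite::write_json(rep[setdiff(names(rep), "points")],
                           file.path(config$out_dir,
                                     "dose_volume_report.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      rep
    }
  })

  # -- matched pairs --------------------------------------------------------
  pair_results <- run_stage(state, "match", {
    probes <- config$probes %||% intersect(
      c("max_heart_dose", "mean_heart_dose", "v20_ipsilateral_lung"),
      colnames(mm$x))
    res <- list()
    for (probe in probes) {
      pairs <- select_pairs(mm, probe, summary_tab,
                            threshold = config$pairing_threshold)
      values <- setNames(mm$x[, probe], mm$patient_id)
      test <- if (nrow(pairs) >= 2) paired_test(pairs, values) else
        list(t = NA_real_, p_value = NA_real_, n_pairs = nrow(pairs),
             degenerate = TRUE)
      write.csv(cbind(as.data.frame(pairs),
                      probe_event = values[pairs$id_event],
                      probe_control = values[pairs$id_control]),
                file.path(config$out_dir, paste0("pairs_", probe, ".csv")),
                row.names = FALSE)
      res[[probe]] <- c(list(probe = probe,
                             n_candidates = attr(pairs, "n_candidates")),
                        test)
    }
    jsonlite::write_json(res, file.path(config$out_dir, "pair_tests.json"),
                         auto_unbox = TRUE, digits = NA)
    res
  })

  jsonlite::write_json(list(seed = config$seed, config_hash = config_hash,
                            n_patients = nrow(mm$x), B = config$B,
                            grid_mode = config$grid_mode),
                       file.path(config$out_dir, "run_info.json"),
                       auto_unbox = TRUE, digits = NA)
  pipeline_log(state, "pipeline complete")
  invisible(list(cohort = cohort, matrix = mm, screen = screen,
                 trained = trained, attribution = summary_tab,
                 dose_volume = dosevol, pairs = pair_results))
}
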