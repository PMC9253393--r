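#' CTCAE v4.0 lymphopenia grade
#'
#' Grades a post-radiotherapy lymphocyte count (cells per microlitre) against
#' the CTCAE v4.0 cutpoints: grade 0 for counts at or above the lower limit of
#' normal (LLN), grade 1 for `[800, LLN)`, grade 2 for `[500, 800)`, grade 3
#' for `[200, 500)` and grade 4 below 200. The binary lymphopenia event used
#' throughout the pipeline is grade >= 1.
#'
#' @param count Numeric vector of lymphocyte counts per microlitre; `NA`
#'   propagates.
#' @param lower_limit_normal LLN per microlitre, must exceed 800
#'   (default 1000).
#' @return Integer vector of grades in 0..4.
#' @export
grade_lymphopenia <- function(count, lower_limit_normal = 1000) {
  stopifnot(is_scalar_number(lower_limit_normal))
  if (lower_limit_normal <= 800) {
    stop_bad_arg("lower_limit_normal must exceed 800 per microlitre")
  }
  if (any(count < 0, na.rm = TRUE)) {
    stop_bad_arg("negative lymphocyte counts are invalid")
  }
  g <- ifelse(count >= lower_limit_normal, 0L,
       ifelse(count >= 800, 1L,
       ifelse(count >= 500, 2L,
       ifelse(count >= 200, 3L, 4L))))
  as.integer(g)
}

#' Encode a cohort into a model matrix
#'
#' Builds the numeric design matrix: continuous features pass through
#' unscaled; each categorical feature contributes one 0/1 indicator per
#' non-reference level (the reference level is never emitted). Missing values
#' are preserved as `NA` — the tree learner consumes them natively, while the
#' penalised-regression fitter restricts itself to the complete-case rows
#' flagged here.
#'
#' @param data Cohort data.frame (as `ril_cohort$data`) or a `ril_cohort`.
#' @param schema A `ril_schema`; taken from the cohort when omitted.
#' @param outcome Name of the binary outcome column (default `"lymphopenia"`).
#' @return Object of class `ril_model_matrix`: list with `x` (numeric matrix),
#'   `outcome` (0/1 vector), `patient_id`, `complete` (logical complete-case
#'   flag per row), and `columns` (data.frame mapping columns to feature,
#'   level and group).
#' @export
encode_cohort <- function(data, schema = NULL, outcome = "lymphopenia") {
  if (inherits(data, "ril_cohort")) {
    schema <- schema %||% data$schema
    data <- data$data
  }
  stopifnot(is.data.frame(data), is.data.frame(schema))
  missing_features <- setdiff(schema$name, names(data))
  if (length(missing_features)) {
    stop_bad_arg("cohort lacks features named in schema: ",
                 paste(missing_features, collapse = ", "))
  }
  if (!outcome %in% names(data)) stop_bad_arg("outcome column not found")
  y <- data[[outcome]]
  stopifnot(all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) stop_bad_arg("outcome must have both classes")

  cols <- list(); colinfo <- list()
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    if (schema$kind[i] == "continuous") {
      cols[[nm]] <- as.numeric(data[[nm]])
      colinfo[[nm]] <- data.frame(column = nm, feature = nm,
                                  level = NA_character_,
                                  group = schema$group[i],
                                  stringsAsFactors = FALSE)
    } else {
      levs <- schema_levels(schema, nm)
      ref <- schema$reference[i]
      vals <- as.character(data[[nm]])
      unseen <- setdiff(unique(vals[!is.na(vals)]), levs)
      if (length(unseen)) {
        stop_bad_arg("feature '", nm, "' has level(s) not in schema: ",
                     paste(unseen, collapse = ", "))
      }
      for (lv in setdiff(levs, ref)) {
        cn <- paste0(nm, ":", lv)
        cols[[cn]] <- ifelse(is.na(vals), NA_real_, as.numeric(vals == lv))
        colinfo[[cn]] <- data.frame(column = cn, feature = nm, level = lv,
                                    group = schema$group[i],
                                    stringsAsFactors = FALSE)
      }
    }
  }
  x <- do.call(cbind, cols)
  rownames(x) <- data$patient_id %||% as.character(seq_len(nrow(data)))
  all_missing <- colSums(!is.na(x)) == 0
  if (any(all_missing)) {
    stop_bad_arg("all-missing column(s): ",
                 paste(colnames(x)[all_missing], collapse = ", "))
  }
  structure(list(x = x, outcome = as.integer(y),
                 patient_id = rownames(x),
                 complete = complete.cases(x),
                 columns = do.call(rbind, c(colinfo,
                                            list(make.row.names = FALSE)))),
            class = "ril_model_matrix")
}

#' @export
print.ril_model_matrix <- function(x, ...) {
  cat(sprintf("<ril_model_matrix> %d patients x %d columns (%d complete cases, %d events)\n",
              nrow(x$x), ncol(x$x), sum(x$complete), sum(x$outcome)))
  invisible(x)
}

#' Subset a model matrix to a set of columns or rows
#'
#' @param mm A `ril_model_matrix`.
#' @param columns Character vector of column names to keep (default all).
#' @param rows Integer or logical row index (default all).
#' @return A `ril_model_matrix` view.
#' @export
subset_matrix <- function(mm, columns = colnames(mm$x), rows = NULL) {
  stopifnot(inherits(mm, "ril_model_matrix"))
  stopifnot(all(columns %in% colnames(mm$x)))
  rows <- rows %||% seq_len(nrow(mm$x))
  x <- mm$x[rows, columns, drop = FALSE]
  structure(list(x = x, outcome = mm$outcome[rows],
                 patient_id = mm$patient_id[rows],
                 complete = complete.cases(x),
                 columns = mm$columns[mm$columns$column %in% columns, ,
                                      drop = FALSE]),
            class = "ril_model_matrix")
}

#' Split a model matrix into the five feature-group views
#'
#' Returns column-disjoint views (clinical, tumor, blood, radiotherapy,
#' treatment) whose union of columns is the full matrix. An empty group yields
#' an empty view, not an error; a column with no group assignment is rejected.
#'
#' @param mm A `ril_model_matrix` from [encode_cohort()].
#' @return Named list of five `ril_model_matrix` views.
#' @export
split_groups <- function(mm) {
  stopifnot(inherits(mm, "ril_model_matrix"))
  groups <- c("clinical", "tumor", "blood", "radiotherapy", "treatment")
  unassigned <- setdiff(colnames(mm$x), mm$columns$column)
  bad_group <- setdiff(unique(mm$columns$group), groups)
  if (length(unassigned) || length(bad_group)) {
    stop_bad_arg("columns without a valid group assignment: ",
                 paste(c(unassigned, bad_group), collapse = ", "))
  }
  out <- lapply(groups, function(g) {
    subset_matrix(mm, columns = mm$columns$column[mm$columns$group == g])
  })
  names(out) <- groups
  out
}

#' Decode categorical indicator columns back to levels
#'
#' Inverse of the k-1 dummy encoding for one categorical feature: rows with
#' all indicators 0 map to the reference level; a single 1 maps to that level.
#'
#' @param mm A `ril_model_matrix`.
#' @param feature Categorical feature name.
#' @param schema The `ril_schema` used for encoding.
#' @return Character vector of levels (`NA` where any indicator was missing).
#' @export
decode_categorical <- function(mm, feature, schema) {
  info <- mm$columns[mm$columns$feature == feature, , drop = FALSE]
  if (!nrow(info)) stop_bad_arg("feature not in matrix: ", feature)
  ref <- schema$reference[schema$name == feature]
  ind <- mm$x[, info$column, drop = FALSE]
  unname(apply(ind, 1L, function(r) {
    if (anyNA(r)) return(NA_character_)
    hit <- which(r == 1)
    if (!length(hit)) ref else info$level[hit[1]]
  }))
}
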