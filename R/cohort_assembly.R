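# Canonical 12-feature / 14-column layout of the design matrix. The size
# profile is ONE selectable feature spanning three columns: its three
# counts are always selected or dropped together.
CANONICAL_FEATURE_MAP <- list(
  age              = "age",
  gender           = "gender",
  cis_type         = "cis_type",
  edss             = "edss",
  lesion_count     = "lesion_count",
  lesion_load      = "lesion_load",
  mean_pd          = "mean_pd",
  mean_t2          = "mean_t2",
  mean_dist_center = "mean_dist_center",
  central_cube     = "central_cube",
  min_axis_dist    = "min_axis_dist",
  size_profile     = c("n_small", "n_medium", "n_large")
)

#' Names of the twelve canonical features
#' @return Character vector of feature names in canonical order.
#' @export
canonical_features <- function() names(CANONICAL_FEATURE_MAP)

#' Encode the clinical sub-vector of one patient
#'
#' Gender is coded 1 = male, 0 = female; the CIS presentation type is
#' coded 1 = optic neuritis, 2 = spinal cord, 3 = brainstem, 4 = other (an
#' arbitrary ordinal coding kept as a single column); age in years and
#' EDSS enter raw.
#'
#' @param record a `patient_record` (or any list with `age`, `gender`,
#'   `cis_type`, `edss`).
#' @return Named numeric vector `c(age, gender, cis_type, edss)`.
#' @export
encode_clinical <- function(record) {
  gender <- switch(tolower(record$gender),
                   male = 1, female = 0,
                   stop("unknown gender: ", record$gender))
  cis <- switch(tolower(record$cis_type),
                optic_neuritis = 1, spinal_cord = 2, brainstem = 3, other = 4,
                stop("unknown CIS category: ", record$cis_type))
  if (record$edss < 0 || record$edss > 10)
    stop("EDSS must lie in [0, 10]")
  c(age = as.numeric(record$age), gender = gender, cis_type = cis,
    edss = as.numeric(record$edss))
}

#' Cohort design matrix
#'
#' Container for a fully assembled cohort: ids, an n x p numeric matrix,
#' labels coded +1 (converter) / -1 (non-converter), a horizon tag and a
#' feature map (feature name -> column names) used by subset selection.
#'
#' @param ids character vector of patient ids.
#' @param X numeric matrix with column names.
#' @param y numeric labels in \{+1, -1\}.
#' @param horizon follow-up tag ("1y", "3y" or NA).
#' @param feature_map named list mapping selectable features to column
#'   names; defaults to one feature per column.
#' @return A `cohort_matrix` object.
#' @export
cohort_matrix <- function(ids, X, y, horizon = NA_character_,
                          feature_map = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X must have column names")
  if (anyNA(X)) stop("design matrix must have no missing values")
  if (length(ids) != nrow(X) || length(y) != nrow(X))
    stop("ids, X and y must agree in length")
  if (!all(y %in% c(-1, 1))) stop("labels must be coded +1 / -1")
  if (is.null(feature_map))
    feature_map <- stats::setNames(as.list(colnames(X)), colnames(X))
  missing_cols <- setdiff(unlist(feature_map), colnames(X))
  if (length(missing_cols))
    stop("feature map refers to unknown columns: ",
         paste(missing_cols, collapse = ", "))
  structure(list(ids = as.character(ids), X = X, y = as.numeric(y),
                 horizon = horizon, feature_map = feature_map),
            class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat(sprintf("<cohort_matrix> %d patients x %d columns (%d features), horizon %s\n",
              nrow(x$X), ncol(x$X), length(x$feature_map), x$horizon))
  cat(sprintf("  converters: %d, non-converters: %d\n",
              sum(x$y == 1), sum(x$y == -1)))
  invisible(x)
}

# column indices of a set of feature names
feature_columns <- function(cohort, features) {
  unknown <- setdiff(features, names(cohort$feature_map))
  if (length(unknown))
    stop("unknown feature(s): ", paste(unknown, collapse = ", "))
  cols <- unlist(cohort$feature_map[features], use.names = FALSE)
  match(cols, colnames(cohort$X))
}

subset_cohort <- function(cohort, rows) {
  cohort_matrix(cohort$ids[rows], cohort$X[rows, , drop = FALSE],
                cohort$y[rows], cohort$horizon, cohort$feature_map)
}

#' Assemble the 14-column design matrix of a cohort
#'
#' Joins the lesion feature table with the clinical records and labels of
#' a chosen horizon into the canonical 12-feature (14-dimension) design
#' matrix: age, gender, cis_type, edss, lesion_count, lesion_load,
#' mean_pd, mean_t2, mean_dist_center, central_cube, min_axis_dist,
#' n_small, n_medium, n_large. Rows are ordered by id, so assembly is
#' invariant to input order.
#'
#' @param feature_table data.frame from [extract_feature_table()].
#' @param cohort list of `patient_record`s supplying clinical fields and
#'   labels (ids must match `feature_table$id` exactly as sets).
#' @param horizon `"1y"` or `"3y"`; every record must carry the
#'   corresponding label.
#' @return A [cohort_matrix()] with the canonical feature map.
#' @export
assemble_design_matrix <- function(feature_table, cohort, horizon = c("1y", "3y")) {
  horizon <- match.arg(horizon)
  ids_clin <- vapply(cohort, `[[`, "", "id")
  if (!setequal(feature_table$id, ids_clin) ||
      anyDuplicated(feature_table$id) || anyDuplicated(ids_clin))
    stop("feature table and cohort ids must match one-to-one")
  ord <- order(feature_table$id)
  ft <- feature_table[ord, , drop = FALSE]
  recs <- cohort[match(ft$id, ids_clin)]

  clin <- t(vapply(recs, encode_clinical, numeric(4)))
  label_field <- paste0("label_", horizon)
  labels <- vapply(recs, function(r) {
    lab <- r[[label_field]]
    if (is.null(lab) || is.na(lab)) stop("missing ", label_field, " for ", r$id)
    lab
  }, "")
  lesion_cols <- c("lesion_count", "lesion_load", "mean_pd", "mean_t2",
                   "mean_dist_center", "central_cube", "min_axis_dist",
                   "n_small", "n_medium", "n_large")
  X <- cbind(clin, as.matrix(ft[, lesion_cols]))
  colnames(X) <- c("age", "gender", "cis_type", "edss", lesion_cols)
  rownames(X) <- NULL
  cohort_matrix(ids = ft$id, X = X,
                y = ifelse(labels == "converter", 1, -1),
                horizon = horizon, feature_map = CANONICAL_FEATURE_MAP)
}

#' Write / read a design matrix as CSV
#'
#' Values are serialised at full double precision (17 significant digits)
#' so a round-trip reproduces the matrix bit-for-bit.
#'
#' @param cohort a [cohort_matrix()].
#' @param path CSV path.
#' @return `path` invisibly (write); a [cohort_matrix()] (read).
#' @export
write_design_matrix <- function(cohort, path) {
  num <- function(x) sub("^(-?\\d+)\\.0*$", "\\1", sprintf("%.17g", x))
  header <- paste(c("id", colnames(cohort$X), "label"), collapse = ",")
  rows <- vapply(seq_len(nrow(cohort$X)), function(i) {
    paste(c(cohort$ids[i], num(cohort$X[i, ]),
            if (cohort$y[i] == 1) "converter" else "non-converter"),
          collapse = ",")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_design_matrix
#' @param feature_map optional feature map for the read matrix; the
#'   canonical map is used when the columns match it.
#' @param horizon horizon tag to attach on read.
#' @export
read_design_matrix <- function(path, horizon = NA_character_,
                               feature_map = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  X <- as.matrix(df[, setdiff(colnames(df), c("id", "label")), drop = FALSE])
  if (is.null(feature_map) &&
      identical(colnames(X), unname(unlist(CANONICAL_FEATURE_MAP))))
    feature_map <- CANONICAL_FEATURE_MAP
  cohort_matrix(df$id, X, ifelse(df$label == "converter", 1, -1),
                horizon, feature_map)
}
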