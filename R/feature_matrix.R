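#' Construct a spectra-by-features intensity matrix
#'
#' The unit of all downstream statistics: rows are spectra (or patient mean
#' profiles), columns are m/z features.
#'
#' @param values Numeric matrix, spectra in rows, features in columns.
#' @param feature_mz Strictly increasing numeric vector of representative m/z
#'   values, one per column.
#' @param patient_id,class_label Per-row metadata vectors.
#' @param region_id Optional per-row region identifiers.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, feature_mz, patient_id, class_label,
                           region_id = patient_id) {
  values <- as.matrix(values)
  if (length(feature_mz) != ncol(values))
    stop("feature_mz length must match the number of columns", call. = FALSE)
  if (length(feature_mz) > 1 && any(diff(feature_mz) <= 0))
    stop("feature_mz must be strictly increasing", call. = FALSE)
  if (length(patient_id) != nrow(values) || length(class_label) != nrow(values))
    stop("per-row metadata must match the number of rows", call. = FALSE)
  if (anyNA(values))
    stop("feature matrix must not contain missing values", call. = FALSE)
  colnames(values) <- sprintf("mz_%.4f", feature_mz)
  structure(list(
    values = values,
    feature_mz = as.numeric(feature_mz),
    patient_id = as.character(patient_id),
    class_label = as.character(class_label),
    region_id = as.character(region_id)
  ), class = "feature_matrix")
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d spectra x %d features (m/z %.1f-%.1f)\n",
              nrow(x$values), ncol(x$values),
              min(x$feature_mz), max(x$feature_mz)))
  print(table(class = x$class_label))
  invisible(x)
}

#' Subset a feature matrix
#'
#' @param fm A [feature_matrix()].
#' @param rows Row indices (default all).
#' @param features m/z values to retain, matched exactly against
#'   `feature_mz` (default all).
#' @return A `feature_matrix`.
#' @export
fm_subset <- function(fm, rows = NULL, features = NULL) {
  ri <- if (is.null(rows)) seq_len(nrow(fm$values)) else rows
  ci <- seq_along(fm$feature_mz)
  if (!is.null(features)) {
    ci <- match(features, fm$feature_mz)
    if (anyNA(ci))
      stop(sprintf("features not present in matrix: %s",
                   paste(features[is.na(ci)], collapse = ", ")),
           call. = FALSE)
    ci <- sort(ci)
  }
  fm_cols(fm_rows(fm, ri), ci)
}

# index-based row/column subsetting (internal)
fm_rows <- function(fm, ri) {
  feature_matrix(fm$values[ri, , drop = FALSE], fm$feature_mz,
                 fm$patient_id[ri], fm$class_label[ri], fm$region_id[ri])
}

fm_cols <- function(fm, ci) {
  feature_matrix(fm$values[, ci, drop = FALSE], fm$feature_mz[ci],
                 fm$patient_id, fm$class_label, fm$region_id)
}

#' Restrict a feature matrix to two class labels
#'
#' @param fm A [feature_matrix()].
#' @param classes Character vector of labels to keep.
#' @return A `feature_matrix` with only the requested classes.
#' @export
fm_classes <- function(fm, classes) {
  keep <- fm$class_label %in% classes
  if (!any(keep)) stop("no rows carry the requested class labels", call. = FALSE)
  fm_subset(fm, rows = which(keep))
}

#' Write / read a feature matrix as CSV
#'
#' Columns are `patient_id`, `class_label`, `region_id` followed by one
#' `mz_<value>` column per feature.
#'
#' @param fm A [feature_matrix()].
#' @param path CSV file path.
#' @return `write_feature_matrix` returns `path` invisibly;
#'   `read_feature_matrix` returns a `feature_matrix`.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(patient_id = fm$patient_id, class_label = fm$class_label,
                   region_id = fm$region_id, fm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  fcols <- grep("^mz_", names(df))
  feature_matrix(as.matrix(df[, fcols, drop = FALSE]),
                 as.numeric(sub("^mz_", "", names(df)[fcols])),
                 df$patient_id, df$class_label, df$region_id)
}
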