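#' Signed log2 fold change of two group means
#'
#' @param mean_a,mean_b Positive group mean intensities; `mean_a` is the
#'   numerator. Antisymmetric under argument swap.
#' @return `log2(mean_a / mean_b)`.
#' @export
log2_fold_change <- function(mean_a, mean_b) {
  if (any(!is.finite(mean_a)) || any(!is.finite(mean_b)) ||
      any(mean_a <= 0) || any(mean_b <= 0))
    stop("log2 fold change requires positive group means", call. = FALSE)
  log2(mean_a / mean_b)
}

#' Fold-change table for a pairwise comparison
#'
#' One record per feature: arithmetic mean intensity over all spectra of each
#' group and the signed `log2(mean_a / mean_b)`. The numerator group is an
#' explicit argument — published discriminator tables use different
#' orientations in different comparison blocks, so orientation is never
#' guessed.
#'
#' @param fm A [feature_matrix()] with spectrum-level rows.
#' @param group_a,group_b Class labels; `group_a` is the numerator.
#' @param features Optional m/z values to report (default: all features).
#' @return A data frame of class `fold_change_table` with columns
#'   `feature_mz`, `mean_group_a`, `mean_group_b`, `log2_fold_change`, and
#'   the group names as attributes and columns.
#' @export
fold_change_table <- function(fm, group_a, group_b, features = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  ia <- fm$class_label == group_a
  ib <- fm$class_label == group_b
  if (!any(ia)) stop(sprintf("group '%s' is empty", group_a), call. = FALSE)
  if (!any(ib)) stop(sprintf("group '%s' is empty", group_b), call. = FALSE)
  if (!is.null(features)) fm2 <- fm_subset(fm, features = features)
  else fm2 <- fm
  ma <- colMeans(fm2$values[ia, , drop = FALSE])
  mb <- colMeans(fm2$values[ib, , drop = FALSE])
  structure(data.frame(feature_mz = fm2$feature_mz,
                       group_a = group_a, group_b = group_b,
                       mean_group_a = as.numeric(ma),
                       mean_group_b = as.numeric(mb),
                       log2_fold_change = log2_fold_change(as.numeric(ma),
                                                           as.numeric(mb)),
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("fold_change_table", "data.frame"))
}

# round-half-up to integer percent, matching published accuracy tables
percent_round <- function(x) as.integer(floor(100 * x + 0.5))

#' Accuracy summary table across models and CV designs
#'
#' Collapses a list of `cv_result` objects into the standard report layout —
#' one row per (level, model, CV design) with the accuracy as an integer
#' percentage (rounded half-up).
#'
#' @param results List of `cv_result` objects (see [cross_validate()]).
#' @param selection Optional character vector (recycled) describing the
#'   feature-selection method behind each result.
#' @return A data frame sorted by (level, model, design) with columns
#'   `level`, `model`, `selection`, `cv`, `n_features`, `accuracy_pct`.
#' @export
accuracy_table <- function(results, selection = NA_character_) {
  stopifnot(length(results) >= 1)
  selection <- rep_len(selection, length(results))
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    design <- switch(r$scheme$design,
                     loo = "LOOCV",
                     kfold = sprintf("k-fold (k = %d)", r$scheme$k),
                     holdout = "holdout")
    data.frame(level = r$scheme$unit, model = toupper(r$model$kind),
               selection = selection[i], cv = design,
               n_features = r$n_features_used,
               accuracy_pct = percent_round(r$accuracy),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$level, out$model, out$cv), , drop = FALSE]
}

#' Load the published peak-discriminator reference table
#'
#' Average group intensities and printed log2 fold changes of the major m/z
#' peak discriminators from a published melanoma BRAF/NRAS MALDI-IMS
#' profiling study, shipped with the package as a worked example of the
#' fold-change arithmetic. The numerator group of each block is recorded
#' explicitly (`mean_numerator` / `mean_denominator`).
#'
#' @return A data frame with columns `comparison`, `mz`, `numerator_group`,
#'   `denominator_group`, `mean_numerator`, `mean_denominator`,
#'   `log2fc_printed`.
#' @export
reported_discriminators <- function() {
  read.csv(system.file("extdata", "reported_discriminators.csv",
                       package = "maldiclass"),
           stringsAsFactors = FALSE)
}
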