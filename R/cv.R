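#' Specify a cross-validation design
#'
#' @param design `"loo"` (leave-one-unit-out), `"kfold"`, or `"holdout"`
#'   (single stratified split, the no-cross-validation check).
#' @param k Number of folds (k-fold only; published designs use 4 and 10).
#' @param unit Evaluation unit: `"spectrum"` (individual spectra) or
#'   `"patient"` (per-patient mean profiles; all spectra of a patient always
#'   travel together).
#' @param holdout_fraction Fraction of units held out (holdout only).
#' @param stratify Stratify the random k-fold partition by class (default
#'   `FALSE`: plain seeded random equisized groups).
#' @param seed Integer seed for the random partition / split.
#' @return An object of class `cv_scheme`.
#' @export
cv_scheme <- function(design = c("loo", "kfold", "holdout"), k = NULL,
                      unit = c("spectrum", "patient"),
                      holdout_fraction = NULL, stratify = FALSE, seed = 1L) {
  design <- match.arg(design)
  unit <- match.arg(unit)
  if (design == "kfold" && (!is_count(k) || k < 2))
    stop("k must be a count >= 2 for k-fold", call. = FALSE)
  if (design == "holdout" &&
      (!is_number(holdout_fraction) || holdout_fraction <= 0 ||
       holdout_fraction >= 1))
    stop("holdout_fraction must lie in (0, 1)", call. = FALSE)
  structure(list(design = design, k = if (!is.null(k)) as.integer(k),
                 unit = unit, holdout_fraction = holdout_fraction,
                 stratify = isTRUE(stratify), seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Seeded k-fold partition
#'
#' Randomly partitions `n` units into `k` disjoint groups whose sizes differ
#' by at most one.
#'
#' @param n Number of units.
#' @param k Number of folds (`2 <= k <= n`).
#' @param seed Integer seed.
#' @param labels Optional class labels for stratified assignment.
#' @param stratify Stratify by `labels`.
#' @return Integer vector of fold ids in `1:k`, one per unit.
#' @export
make_folds <- function(n, k, seed = 1L, labels = NULL, stratify = FALSE) {
  if (!is_count(k) || k < 2 || k > n)
    stop("need 2 <= k <= n", call. = FALSE)
  folds <- integer(n)
  with_seed(seed, {
    if (stratify && !is.null(labels)) {
      # round-robin over a permutation within each class, offset so classes
      # do not all start filling fold 1
      offset <- 0L
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        folds[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
        offset <- offset + length(idx)
      }
    } else {
      sizes <- rep(n %/% k, k)
      extra <- n %% k
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      folds[sample.int(n)] <- rep(seq_len(k), times = sizes)
    }
  })
  folds
}

#' Per-patient mean profiles
#'
#' Collapses a spectra-level feature matrix to one row per patient, each the
#' feature-wise arithmetic mean of that patient's spectra — the analysis unit
#' of patient-level classification. Patients appear in order of first
#' appearance.
#'
#' @param fm A [feature_matrix()] with per-spectrum rows.
#' @return A [feature_matrix()] with one row per patient.
#' @export
patient_mean_profiles <- function(fm) {
  pats <- unique(fm$patient_id)
  rows <- matrix(0, nrow = length(pats), ncol = ncol(fm$values))
  labs <- character(length(pats))
  for (i in seq_along(pats)) {
    idx <- fm$patient_id == pats[i]
    lab <- unique(fm$class_label[idx])
    if (length(lab) != 1)
      stop(sprintf("patient '%s' carries conflicting class labels: %s",
                   pats[i], paste(lab, collapse = ", ")), call. = FALSE)
    rows[i, ] <- colMeans(fm$values[idx, , drop = FALSE])
    labs[i] <- lab
  }
  feature_matrix(rows, fm$feature_mz, pats, labs, pats)
}

cv_units <- function(fm, unit) {
  # spectrum-level: each row is a unit; patient-level: collapse to mean
  # profiles first (if not already one row per patient)
  if (unit == "patient" && anyDuplicated(fm$patient_id))
    fm <- patient_mean_profiles(fm)
  fm
}

new_cv_result <- function(confusion, per_fold, scheme, model, n_features) {
  structure(list(confusion = confusion,
                 accuracy = sum(diag(confusion)) / sum(confusion),
                 per_fold_accuracy = per_fold,
                 scheme = scheme, model = model,
                 n_features_used = n_features),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  lab <- switch(x$scheme$design,
                loo = "LOOCV",
                kfold = sprintf("k-fold (k = %d)", x$scheme$k),
                holdout = sprintf("holdout (%.0f%%)",
                                  100 * x$scheme$holdout_fraction))
  cat(sprintf("<cv_result> %s %s, %s level, %d features: accuracy %.1f%%\n",
              toupper(x$model$kind), lab, x$scheme$unit, x$n_features_used,
              100 * x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' Cross-validate a classifier on a feature matrix
#'
#' Leave-one-out fits one model per unit, each tested on the held-out unit;
#' k-fold partitions units into `k` seeded random equisized groups, each
#' serving once as the test set. Predictions are pooled over folds and the
#' reported accuracy is computed from the pooled confusion table (not the
#' mean of fold accuracies). With `unit = "patient"`, spectra are first
#' collapsed to per-patient mean profiles, so no patient ever contributes to
#' both the training and the test side of a fold.
#'
#' @param fm A two-class [feature_matrix()] (spectra or patient profiles).
#' @param spec A [model_spec()].
#' @param scheme A [cv_scheme()] with design `"loo"` or `"kfold"`.
#' @return A `cv_result`: pooled 2x2 `confusion` (rows truth, columns
#'   prediction), `accuracy`, `per_fold_accuracy`, and the scheme/model used.
#' @export
cross_validate <- function(fm, spec, scheme) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(spec, "model_spec"),
            inherits(scheme, "cv_scheme"))
  if (scheme$design == "holdout")
    return(holdout_evaluate(fm, spec, scheme$holdout_fraction, scheme$seed,
                            unit = scheme$unit))
  fm <- cv_units(fm, scheme$unit)
  n <- nrow(fm$values)
  classes <- sort(unique(fm$class_label))
  if (length(classes) != 2)
    stop("exactly two classes required", call. = FALSE)
  if (min(table(fm$class_label)) < 2)
    stop("need >= 2 units per class", call. = FALSE)

  folds <- if (scheme$design == "loo") seq_len(n)
           else make_folds(n, scheme$k, scheme$seed, fm$class_label,
                           scheme$stratify)
  k <- max(folds)
  pred <- character(n)
  per_fold <- numeric(k)
  for (f in seq_len(k)) {
    test <- folds == f
    ytr <- fm$class_label[!test]
    if (length(unique(ytr)) < 2)
      stop(sprintf("training set of fold %d contains a single class (seed %d)",
                   f, scheme$seed), call. = FALSE)
    fit <- fit_model(spec, fm$values[!test, , drop = FALSE], ytr)
    pred[test] <- predict(fit, fm$values[test, , drop = FALSE])
    per_fold[f] <- mean(pred[test] == fm$class_label[test])
  }
  confusion <- table(truth = factor(fm$class_label, levels = classes),
                     prediction = factor(pred, levels = classes))
  new_cv_result(confusion, per_fold, scheme, spec, ncol(fm$values))
}

#' Single stratified holdout evaluation (no cross-validation)
#'
#' Splits the units once into a training and a held-out part by stratified
#' random sampling, trains on the former and reports accuracy on the latter.
#' This mirrors the overfitting check in which a classification without
#' cross-validation is compared against cross-validated results.
#'
#' @param fm A two-class [feature_matrix()].
#' @param spec A [model_spec()].
#' @param holdout_fraction Fraction of each class held out for testing.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @param unit Evaluation unit, as in [cv_scheme()].
#' @return A `cv_result` (single "fold" = the held-out part).
#' @export
holdout_evaluate <- function(fm, spec, holdout_fraction, seed = 1L,
                             unit = "spectrum") {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!is_number(holdout_fraction) || holdout_fraction <= 0 ||
      holdout_fraction >= 1)
    stop("holdout_fraction must lie in (0, 1)", call. = FALSE)
  fm <- cv_units(fm, unit)
  classes <- sort(unique(fm$class_label))
  if (length(classes) != 2)
    stop("exactly two classes required", call. = FALSE)
  test <- logical(nrow(fm$values))
  with_seed(seed, {
    for (cl in classes) {
      idx <- which(fm$class_label == cl)
      n_test <- round(holdout_fraction * length(idx))
      if (n_test < 1 || n_test >= length(idx))
        stop(sprintf("holdout fraction leaves < 1 unit of class '%s' on one side",
                     cl), call. = FALSE)
      test[sample(idx, n_test)] <- TRUE
    }
  })
  fit <- fit_model(spec, fm$values[!test, , drop = FALSE],
                   fm$class_label[!test])
  pred <- predict(fit, fm$values[test, , drop = FALSE])
  confusion <- table(truth = factor(fm$class_label[test], levels = classes),
                     prediction = factor(pred, levels = classes))
  scheme <- cv_scheme("holdout", unit = unit,
                      holdout_fraction = holdout_fraction, seed = seed)
  new_cv_result(confusion, sum(diag(confusion)) / sum(confusion), scheme,
                spec, ncol(fm$values))
}
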