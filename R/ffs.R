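#' Greedy wrapper forward feature selection
#'
#' Starting from the empty set, every remaining feature is tentatively added
#' and the cross-validated accuracy of the model on the enlarged set is
#' computed; the best addition is kept (ties broken toward the lowest m/z).
#' Selection stops when the best improvement over the previous step falls
#' below `min_improvement` or when `max_features` have been selected. The
#' internal accuracy criterion is the same cross-validation design requested
#' for final evaluation, which avoids the selection bias of resubstitution
#' accuracy. The whole trace is deterministic for a fixed scheme seed.
#'
#' @param fm A two-class [feature_matrix()].
#' @param spec A [model_spec()].
#' @param scheme A [cv_scheme()] used to score candidate sets.
#' @param max_features Maximum number of features to select (default 30).
#' @param min_improvement Minimum accuracy gain required to continue
#'   (default 0.001); the first feature is always accepted.
#' @return An object of class `ffs_trace`: `selected_mz` (in selection
#'   order), `cv_accuracy_at_step`, and `stop_reason` (`"max_features"` or
#'   `"improvement_below_threshold"`).
#' @export
forward_feature_selection <- function(fm, spec, scheme, max_features = 30,
                                      min_improvement = 0.001) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (ncol(fm$values) < 2)
    stop("need >= 2 candidate features", call. = FALSE)
  if (!is_count(max_features))
    stop("max_features must be a count >= 1", call. = FALSE)
  fm <- cv_units(fm, scheme$unit)   # collapse once so every step sees the
                                    # same units and folds
  p <- ncol(fm$values)
  max_features <- min(max_features, p)
  selected <- integer(0)
  accs <- numeric(0)
  stop_reason <- "max_features"
  repeat {
    remaining <- setdiff(seq_len(p), selected)
    cand_acc <- vapply(remaining, function(j) {
      cross_validate(fm_cols(fm, sort(c(selected, j))), spec, scheme)$accuracy
    }, numeric(1))
    best <- remaining[which.max(cand_acc)]  # which.max: first max = lowest mz
    best_acc <- max(cand_acc)
    prev <- if (length(accs)) accs[length(accs)] else 0
    if (length(selected) > 0 && best_acc - prev < min_improvement) {
      stop_reason <- "improvement_below_threshold"
      break
    }
    selected <- c(selected, best)
    accs <- c(accs, best_acc)
    if (length(selected) >= max_features) {
      stop_reason <- "max_features"
      break
    }
  }
  structure(list(selected_mz = fm$feature_mz[selected],
                 cv_accuracy_at_step = accs,
                 stop_reason = stop_reason,
                 model = spec, scheme = scheme),
            class = "ffs_trace")
}

#' @export
print.ffs_trace <- function(x, ...) {
  cat(sprintf("<ffs_trace> %d features selected (%s)\n",
              length(x$selected_mz), x$stop_reason))
  print(data.frame(step = seq_along(x$selected_mz),
                   feature_mz = x$selected_mz,
                   cv_accuracy = x$cv_accuracy_at_step))
  invisible(x)
}
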