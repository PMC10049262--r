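#' Per-feature AUROC scores
#'
#' For every feature, computes the area under the ROC curve via the
#' Mann-Whitney rank identity `U / (n1 * n0)` with ties counted 1/2:
#' `auc_raw` is the probability that a random positive-class value exceeds a
#' random negative-class value. Because a feature can discriminate in either
#' direction, the folded score `max(auc_raw, 1 - auc_raw)` is what threshold
#' selection operates on.
#'
#' @param fm A two-class [feature_matrix()].
#' @param positive_label The label treated as the positive class.
#' @return A data frame of class `auroc_scores` with columns `feature_mz`,
#'   `auc_raw`, `auc_folded`, in the input feature order.
#' @export
auroc_per_feature <- function(fm, positive_label) {
  labs <- unique(fm$class_label)
  if (length(labs) != 2)
    stop(sprintf("exactly two class labels required, found %d", length(labs)),
         call. = FALSE)
  if (!positive_label %in% labs)
    stop(sprintf("positive label '%s' not present", positive_label),
         call. = FALSE)
  pos <- fm$class_label == positive_label
  n1 <- sum(pos); n0 <- sum(!pos)
  auc <- apply(fm$values, 2, function(x) {
    r <- rank(x)                      # midranks handle ties as 1/2
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  })
  structure(data.frame(feature_mz = fm$feature_mz,
                       auc_raw = as.numeric(auc),
                       auc_folded = pmax(auc, 1 - auc),
                       row.names = NULL),
            class = c("auroc_scores", "data.frame"),
            positive_label = positive_label)
}

#' Threshold features by folded AUROC
#'
#' @param scores An `auroc_scores` data frame from [auroc_per_feature()].
#' @param threshold Folded-AUROC cutoff in `[0.5, 1]` (published workflows
#'   use values such as 0.7, 0.73, 0.8, 0.84).
#' @return The subset of `scores` with `auc_folded >= threshold`, order
#'   preserved (possibly zero rows).
#' @export
filter_by_auroc <- function(scores, threshold) {
  stopifnot(inherits(scores, "auroc_scores") || is.data.frame(scores))
  if (!is_number(threshold) || threshold < 0.5 || threshold > 1)
    stop("threshold must lie in [0.5, 1]", call. = FALSE)
  scores[scores$auc_folded >= threshold, , drop = FALSE]
}
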