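#' Specify a classification model
#'
#' Two linear classifiers are supported, matching common practice for
#' high-dimensional peptide profiles:
#' \describe{
#'   \item{`lda`}{two-class linear discriminant with a shrinkage pooled
#'     covariance estimator, well-defined when features outnumber samples.
#'     `shrinkage = "auto"` uses the Ledoit-Wolf estimate toward the scaled
#'     identity; a number in `[0, 1]` fixes the shrinkage intensity. Uniform
#'     class priors are used, so leave-one-out evaluation is not biased by
#'     the held-out unit's class being underrepresented in training.}
#'   \item{`svm`}{soft-margin linear support vector machine
#'     (\pkg{e1071}/libsvm), cost `cost`; by default features are
#'     standardized using training-fold statistics only.}
#' }
#'
#' @param kind `"lda"` or `"svm"`.
#' @param shrinkage LDA shrinkage intensity: `"auto"` or a number in `[0,1]`.
#' @param cost SVM soft-margin constant.
#' @param standardize Standardize features with training statistics (SVM).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(kind = c("lda", "svm"), shrinkage = "auto",
                       cost = 1, standardize = TRUE) {
  kind <- match.arg(kind)
  if (kind == "lda") {
    ok <- identical(shrinkage, "auto") ||
      (is_number(shrinkage) && shrinkage >= 0 && shrinkage <= 1)
    if (!ok) stop("shrinkage must be \"auto\" or a number in [0, 1]",
                  call. = FALSE)
  }
  if (kind == "svm" && (!is_number(cost) || cost <= 0))
    stop("cost must be a positive number", call. = FALSE)
  structure(list(kind = kind, shrinkage = shrinkage, cost = cost,
                 standardize = isTRUE(standardize)),
            class = "model_spec")
}

#' Fit a classifier to a training set
#'
#' @param spec A [model_spec()].
#' @param x Numeric training matrix (samples x features).
#' @param y Class labels; exactly two distinct labels must be present.
#' @return A fitted model of class `maldi_lda` or `maldi_svm`, with a
#'   [predict()] method returning one label per row.
#' @export
fit_model <- function(spec, x, y) {
  stopifnot(inherits(spec, "model_spec"))
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2)
    stop(sprintf("training set must contain exactly two classes, found %d",
                 length(classes)), call. = FALSE)
  if (ncol(x) < 1) stop("at least one feature required", call. = FALSE)
  if (spec$kind == "lda") fit_lda(spec, x, y, classes)
  else fit_svm(spec, x, y, classes)
}

# Shrinkage LDA. Pooled within-class covariance with the maximum-likelihood
# denominator n (invariant under sample duplication), shrunk toward the
# scaled identity mu*I. "auto" uses the Ledoit-Wolf (2004) intensity.
fit_lda <- function(spec, x, y, classes) {
  i0 <- y == classes[1]
  m0 <- colMeans(x[i0, , drop = FALSE])
  m1 <- colMeans(x[!i0, , drop = FALSE])
  xc <- x
  xc[i0, ] <- sweep(x[i0, , drop = FALSE], 2, m0)
  xc[!i0, ] <- sweep(x[!i0, , drop = FALSE], 2, m1)
  n <- nrow(x); p <- ncol(x)
  S <- crossprod(xc) / n
  mu <- mean(diag(S))
  lambda <- spec$shrinkage
  if (identical(lambda, "auto")) {
    d2 <- sum((S - diag(mu, p))^2)
    if (d2 <= .Machine$double.eps) {
      lambda <- 0
    } else {
      b2bar <- sum(rowSums(xc^2)^2) / n^2 - sum(S^2) / n
      lambda <- min(b2bar, d2) / d2
    }
  }
  Sshr <- (1 - lambda) * S
  diag(Sshr) <- diag(Sshr) + lambda * mu
  w <- tryCatch(solve(Sshr, m1 - m0), error = function(e) {
    ridge <- max(mu, 1) * 1e-8
    solve(Sshr + diag(ridge, p), m1 - m0)
  })
  structure(list(classes = classes, w = as.numeric(w),
                 threshold = sum(w * (m0 + m1) / 2),
                 lambda = lambda, spec = spec),
            class = "maldi_lda")
}

#' @export
predict.maldi_lda <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  score <- drop(newdata %*% object$w) - object$threshold
  ifelse(score > 0, object$classes[2], object$classes[1])
}

fit_svm <- function(spec, x, y, classes) {
  if (spec$standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, sd)
    scl[!is.finite(scl) | scl < 1e-12] <- 1
    x <- scale(x, center = ctr, scale = scl)
  } else {
    ctr <- NULL; scl <- NULL
  }
  fit <- e1071::svm(x = x, y = factor(y, levels = classes),
                    kernel = "linear", cost = spec$cost, scale = FALSE)
  structure(list(classes = classes, fit = fit, center = ctr, scl = scl,
                 spec = spec),
            class = "maldi_svm")
}

#' @export
predict.maldi_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$center))
    newdata <- scale(newdata, center = object$center, scale = object$scl)
  as.character(predict(object$fit, newdata))
}

#' Principal component scores of a feature matrix
#'
#' Scores of the mean-centered data on the top-variance orthogonal
#' directions, as used for unsupervised inspection of spectral clusters.
#'
#' @param fm A [feature_matrix()].
#' @param n_components Number of components (default 3).
#' @return A list of class `pca_scores`: `scores` (rows x components),
#'   `explained_variance` (non-increasing fractions, all components) and the
#'   row `class_label`s.
#' @export
pca_scores <- function(fm, n_components = 3) {
  x <- fm$values
  if (nrow(x) < n_components || ncol(x) < n_components)
    stop("need at least n_components rows and features", call. = FALSE)
  tot <- sum(apply(x, 2, stats::var))
  if (!is.finite(tot) || tot <= .Machine$double.eps)
    stop("degenerate (constant) matrix: no variance to decompose",
         call. = FALSE)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x[, seq_len(n_components), drop = FALSE],
                 explained_variance = ev,
                 class_label = fm$class_label),
            class = "pca_scores")
}

#' @export
print.pca_scores <- function(x, ...) {
  cat(sprintf("<pca_scores> %d rows x %d components; explained variance: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%",
                            100 * x$explained_variance[seq_len(ncol(x$scores))]),
                    collapse = ", ")))
  invisible(x)
}
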