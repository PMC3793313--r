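# Linear soft-margin SVM via dual coordinate descent.
#
# No SVM implementation ships with the pre-installed R stack, so the package
# carries its own: the standard dual coordinate-descent solver for the
# L1-loss (hinge) linear SVM. The sweep order is fixed, making the fit fully
# deterministic; with the feature count after voxel selection (a few hundred
# at most) the solver converges in a handful of passes.

#' Fit a binary linear SVM (hinge loss, L2 penalty)
#'
#' Minimizes `0.5 ||w||^2 + C * sum_i max(0, 1 - y_i w.x_i)` over the
#' augmented weight vector (a constant bias column is appended internally).
#'
#' @param X numeric matrix, samples x features.
#' @param y labels in `{-1, +1}`.
#' @param C soft-margin cost (default 1).
#' @param max_passes maximum sweeps over the data.
#' @param tol stop when the largest projected gradient magnitude in a sweep
#'   falls below this.
#' @return list with `w` (length `ncol(X)`), `b` (bias), `n_passes`.
#' @export
linear_svm_fit <- function(X, y, C = 1, max_passes = 1000L, tol = 1e-6) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(-1, 1)), length(y) == nrow(X))
  Xa <- cbind(X, 1)                      # bias via augmentation
  m <- nrow(Xa)
  Qii <- rowSums(Xa * Xa)
  alpha <- numeric(m)
  w <- numeric(ncol(Xa))
  pass <- 0L
  repeat {
    pass <- pass + 1L
    max_pg <- 0
    for (i in seq_len(m)) {
      G <- y[i] * sum(w * Xa[i, ]) - 1
      PG <- if (alpha[i] == 0) min(G, 0) else if (alpha[i] == C) max(G, 0) else G
      if (abs(PG) > max_pg) max_pg <- abs(PG)
      if (abs(PG) > 1e-12) {
        old <- alpha[i]
        alpha[i] <- min(max(old - G / Qii[i], 0), C)
        w <- w + (alpha[i] - old) * y[i] * Xa[i, ]
      }
    }
    if (max_pg < tol || pass >= max_passes) break
  }
  p <- ncol(X)
  list(w = w[seq_len(p)], b = w[p + 1L], n_passes = pass)
}

#' Fit a one-vs-rest multiclass linear SVM
#'
#' @param X samples x features matrix.
#' @param labels class label per sample.
#' @param C soft-margin cost.
#' @return list with per-class weight matrix `W`, biases `b`, `classes`.
#' @export
svm_ovr_fit <- function(X, labels, C = 1) {
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2L) stop_value("need at least 2 classes")
  W <- matrix(0, nrow = ncol(X), ncol = length(classes))
  b <- numeric(length(classes))
  for (j in seq_along(classes)) {
    yj <- ifelse(labels == classes[j], 1, -1)
    fit <- linear_svm_fit(X, yj, C = C)
    W[, j] <- fit$w
    b[j] <- fit$b
  }
  list(W = W, b = b, classes = classes)
}

#' Predict class labels from a one-vs-rest linear SVM
#'
#' @param model fit from [svm_ovr_fit()].
#' @param X samples x features matrix.
#' @return character vector of predicted labels (largest decision value;
#'   ties to the first class in sorted order).
#' @export
svm_ovr_predict <- function(model, X) {
  scores <- as.matrix(X) %*% model$W +
    matrix(model$b, nrow(X), length(model$b), byrow = TRUE)
  model$classes[max.col(scores, ties.method = "first")]
}
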