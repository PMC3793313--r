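# Decoding evaluation: trial patterns, cross-validated linear-SVM accuracy,
# similarity matrices with per-voxel mean centering, within/between-category
# contrast, and the Wilcoxon signed-rank test for paired method comparisons.

#' Extract per-trial activity patterns
#'
#' Builds one pattern per stimulus trial: the mean signal of the selected
#' voxels over a short window after trial onset. The default window is
#' observations 1-2 post-onset (about 2-4 s at TR 2 s), absorbing the
#' hemodynamic delay. Control, blank and unlabeled intervals are skipped.
#'
#' @param ts a `voxel_ts` of the event-related task runs.
#' @param design the task `design_table`; rows whose condition is not
#'   `"control"`, `"blank"` or `""` are treated as stimulus trials.
#' @param selection a `selected_features` (or integer vector of voxel rows).
#' @param window_offsets integer offsets (in observations) from trial onset
#'   over which the signal is averaged; default `c(1, 2)`.
#' @return an object of class `pattern_set`: `patterns` (m trials x p
#'   voxels), `labels`, `run_id`, `voxels`.
#' @export
extract_patterns <- function(ts, design, selection, window_offsets = c(1L, 2L)) {
  stopifnot(inherits(ts, "voxel_ts"))
  idx <- if (inherits(selection, "selected_features")) selection$indices else
    as.integer(selection)
  if (length(idx) == 0L) stop_value("empty selection")
  if (min(idx) < 1L || max(idx) > nrow(ts$values)) {
    stop_value("selection index out of range")
  }
  trials <- design[!design$condition %in% c("control", "blank", ""), ,
                   drop = FALSE]
  if (nrow(trials) == 0L) stop_value("design contains no stimulus trials")
  run_start <- match(unique(ts$run_id), ts$run_id)
  names(run_start) <- unique(ts$run_id)
  run_len <- table(ts$run_id)
  m <- nrow(trials)
  P <- matrix(NA_real_, m, length(idx))
  for (i in seq_len(m)) {
    r <- as.character(trials$run[i])
    if (!r %in% names(run_start)) stop_value("trial refers to absent run ", r)
    cols_rel <- trials$onset[i] + window_offsets
    if (any(cols_rel < 1L) || any(cols_rel > run_len[[r]])) {
      stop_value("trial window exceeds run ", r, " bounds")
    }
    cols <- run_start[[r]] - 1L + cols_rel
    P[i, ] <- rowMeans(ts$values[idx, cols, drop = FALSE])
  }
  structure(list(patterns = P, labels = trials$condition,
                 run_id = trials$run, voxels = idx),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("<pattern_set> %d patterns x %d voxels, %d categories\n",
              nrow(x$patterns), ncol(x$patterns), length(unique(x$labels))))
  invisible(x)
}

stratified_folds <- function(labels, n_folds, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      members <- which(labels == cl)
      members <- members[sample.int(length(members))]
      fold[members] <- rep_len(seq_len(n_folds), length(members))
    }
  })
  fold
}

#' Cross-validated linear-SVM decoding accuracy
#'
#' Stratified `n_folds`-fold cross-validation: patterns are partitioned into
#' near-equal portions per category with the seeded generator; for each fold
#' a one-vs-rest linear SVM (fixed cost `C`) is trained on the remaining
#' portions — with features standardized by the training split's mean and SD
#' only, so no test-set statistics leak — and scored on the held-out
#' portion. The mean of the fold accuracies estimates the decoder's true
#' accuracy.
#'
#' @param ps a `pattern_set`.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed for the fold partition.
#' @param C SVM soft-margin cost (default 1).
#' @return an object of class `cv_result`: `fold_accuracies`,
#'   `mean_accuracy`, `n_folds`, `seed`.
#' @export
cv_svm_accuracy <- function(ps, n_folds = 5L, seed = 1L, C = 1) {
  stopifnot(inherits(ps, "pattern_set"))
  if (n_folds < 2L) stop_value("n_folds must be >= 2")
  labels <- as.character(ps$labels)
  if (min(table(labels)) < 2L) {
    stop_value("every category needs at least 2 patterns")
  }
  fold <- stratified_folds(labels, n_folds, seed)
  acc <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    if (length(unique(labels[tr])) < length(unique(labels))) {
      stop_value("a class is absent from the training split of fold ", f,
                 "; use a different seed or fewer folds")
    }
    mu <- colMeans(ps$patterns[tr, , drop = FALSE])
    sd <- apply(ps$patterns[tr, , drop = FALSE], 2L, stats::sd)
    sd[sd == 0] <- 1
    Xtr <- sweep(sweep(ps$patterns[tr, , drop = FALSE], 2L, mu), 2L, sd, "/")
    Xte <- sweep(sweep(ps$patterns[!tr, , drop = FALSE], 2L, mu), 2L, sd, "/")
    model <- svm_ovr_fit(Xtr, labels[tr], C = C)
    pred <- svm_ovr_predict(model, Xte)
    acc[f] <- mean(pred == labels[!tr])
  }
  structure(list(fold_accuracies = acc, mean_accuracy = mean(acc),
                 n_folds = n_folds, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> mean accuracy %.3f over %d folds (%s)\n",
              x$mean_accuracy, x$n_folds,
              paste(sprintf("%.2f", x$fold_accuracies), collapse = ", ")))
  invisible(x)
}

#' Pattern similarity matrix with per-voxel centering
#'
#' Normalizes patterns to a mean of zero in each voxel across all patterns
#' (subtracting the mean response over patterns), then computes the pairwise
#' linear correlation between pattern vectors. High positive correlations
#' mark patterns a correlation classifier would put in the same category.
#'
#' @param ps a `pattern_set` with at least 2 patterns.
#' @return an object of class `similarity_matrix`: `values` (m x m,
#'   symmetric, unit diagonal), `labels`.
#' @export
similarity_matrix <- function(ps) {
  stopifnot(inherits(ps, "pattern_set"))
  P <- ps$patterns
  if (nrow(P) < 2L) stop_value("need at least 2 patterns")
  centered <- sweep(P, 2L, colMeans(P))
  pat_sd <- apply(centered, 1L, stats::sd)
  bad <- which(pat_sd == 0)
  if (length(bad) > 0L) {
    stop_value("zero-variance centered pattern for stimulus ",
               paste(utils::head(bad, 5L), collapse = ", "))
  }
  V <- stats::cor(t(centered))
  V <- (V + t(V)) / 2
  diag(V) <- 1
  structure(list(values = V, labels = as.character(ps$labels)),
            class = "similarity_matrix")
}

#' Within- minus between-category correlation contrast
#'
#' Mean of the off-diagonal within-category correlations minus the mean of
#' the between-category correlations: the scalar summary of how much more
#' alike same-category patterns are.
#'
#' @param sm a `similarity_matrix`.
#' @return scalar contrast.
#' @export
within_between_contrast <- function(sm) {
  stopifnot(inherits(sm, "similarity_matrix"))
  labs <- sm$labels
  if (length(unique(labs)) < 2L) stop_value("need >= 2 categories")
  if (min(table(labs)) < 2L) {
    stop_value("every category needs >= 2 patterns for a within-category mean")
  }
  same <- outer(labs, labs, "==")
  offdiag <- !diag(TRUE, length(labs))
  mean(sm$values[same & offdiag]) - mean(sm$values[!same])
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; `|differences|` are ranked with average
#' ranks for ties; the statistic is the positive-rank sum `W+`. For up to
#' `exact_max` nonzero pairs the p-value is computed from the exact null
#' distribution of `W+` over all `2^n` sign assignments (tie-aware, via
#' convolution over doubled ranks — identical to full enumeration);
#' above that, a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param a,b paired numeric vectors of equal length (>= 5 recommended).
#' @param alternative `"greater"` (a tends to exceed b), `"less"`, or
#'   `"two.sided"`.
#' @param exact_max largest n for the exact distribution (default 25).
#' @return list with `statistic` (W+), `p_value`, `n` (nonzero pairs),
#'   `exact` (logical).
#' @export
wilcoxon_signed_rank <- function(a, b,
                                 alternative = c("greater", "less",
                                                 "two.sided"),
                                 exact_max = 25L) {
  alternative <- match.arg(alternative)
  if (length(a) != length(b)) stop_value("a and b must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop_value("all differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    # distribution of 2*W+ over sign assignments: polynomial product
    r2 <- as.integer(round(2 * r))
    maxs <- sum(r2)
    f <- numeric(maxs + 1L)       # f[s + 1] = #assignments with 2*W+ = s
    f[1L] <- 1
    for (rr in r2) {
      shifted <- c(numeric(rr), f[seq_len(maxs + 1L - rr)])
      f <- f + shifted
    }
    total <- 2^n
    w2 <- as.integer(round(2 * W))
    p_ge <- sum(f[(w2 + 1L):(maxs + 1L)]) / total
    p_le <- sum(f[seq_len(w2 + 1L)]) / total
    p <- switch(alternative,
                greater = p_ge,
                less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    sig <- sqrt(sig2)
    p <- switch(alternative,
                greater = stats::pnorm((W - mu - 0.5) / sig,
                                       lower.tail = FALSE),
                less = stats::pnorm((W - mu + 0.5) / sig),
                two.sided = min(1, 2 * min(
                  stats::pnorm((W - mu - 0.5) / sig, lower.tail = FALSE),
                  stats::pnorm((W - mu + 0.5) / sig))))
    exact <- FALSE
  }
  list(statistic = W, p_value = p, n = n, exact = exact)
}
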