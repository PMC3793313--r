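# Principal feature analysis: dependency-matrix eigendecomposition, cosine
# k-means on eigenvector row projections, per-cluster representative
# selection, and the leading-eigenvector noise filter.
#
# The idea: voxels whose time courses are highly correlated project to
# similar row vectors a_i of the truncated eigenvector matrix A_q, so
# clustering the a_i under cosine distance groups redundant voxels together.
# Keeping one original voxel per cluster yields a feature subset that spans
# the dependency structure without duplicating information, and scoring the
# kept voxels by their loading on the leading eigenvector demotes clusters
# made of pure noise.

#' Dependency matrix of a voxel time series
#'
#' Computes the n x n covariance or correlation matrix of the voxel rows of
#' `Y` (observations are the samples; covariance uses divisor `L - 1`).
#' Correlation is the default dependency mode because fMRI voxel variances
#' sit on an arbitrary scanner scale.
#'
#' @param ts a `voxel_ts`, or a bare numeric matrix (voxels x observations).
#' @param mode `"correlation"` (default) or `"covariance"`.
#' @return symmetric n x n matrix.
#' @export
compute_dependency_matrix <- function(ts, mode = c("correlation", "covariance")) {
  mode <- match.arg(mode)
  Y <- if (inherits(ts, "voxel_ts")) ts$values else as.matrix(ts)
  assert_finite_matrix(Y, "Y")
  if (ncol(Y) < 2L) stop_value("need at least 2 observations")
  if (mode == "correlation") {
    v <- apply(Y, 1L, stats::var)
    bad <- which(v == 0)
    if (length(bad) > 0L) {
      stop_value("zero-variance voxel(s) in correlation mode: row ",
                 paste(utils::head(bad, 5L), collapse = ", "))
    }
    sigma <- stats::cor(t(Y))
  } else {
    sigma <- stats::cov(t(Y))
  }
  # cor/cov are symmetric up to representation; enforce exactly
  (sigma + t(sigma)) / 2
}

#' Eigendecompose a dependency matrix
#'
#' Returns eigenpairs sorted by non-increasing eigenvalue, with a fixed sign
#' convention: each eigenvector's entry of largest absolute value is made
#' nonnegative (first such entry on ties). Eigensolvers are sign-ambiguous;
#' the convention makes the row projections, and hence the clustering,
#' reproducible.
#'
#' @param sigma symmetric numeric matrix.
#' @param tol relative asymmetry tolerance.
#' @return an object of class `dependency_eigen` with elements `sigma`,
#'   `eigenvalues` (non-increasing) and `eigenvectors` (unit-norm columns).
#' @export
eigendecompose <- function(sigma, tol = 1e-9) {
  sigma <- as.matrix(sigma)
  assert_finite_matrix(sigma, "sigma")
  scale <- max(abs(sigma), 1e-300)
  if (max(abs(sigma - t(sigma))) > tol * scale) {
    stop_value("sigma is not symmetric within tolerance")
  }
  sigma <- (sigma + t(sigma)) / 2
  ed <- eigen(sigma, symmetric = TRUE)
  A <- ed$vectors
  for (j in seq_len(ncol(A))) {
    i <- which.max(abs(A[, j]))
    if (A[i, j] < 0) A[, j] <- -A[, j]
  }
  structure(
    list(sigma = sigma, eigenvalues = ed$values, eigenvectors = A),
    class = "dependency_eigen"
  )
}

#' @export
print.dependency_eigen <- function(x, ...) {
  cat(sprintf("<dependency_eigen> n = %d, leading eigenvalues: %s\n",
              length(x$eigenvalues),
              paste(signif(utils::head(x$eigenvalues, 5L), 4L),
                    collapse = ", ")))
  invisible(x)
}

#' Number of components retaining a variance fraction
#'
#' Smallest `q` with `sum(lambda[1:q]) / sum(lambda) >= variance_fraction`.
#' Tiny negative eigenvalues (numerical noise) are clamped to zero first.
#'
#' @param eigenvalues non-increasing eigenvalue vector.
#' @param variance_fraction target fraction in (0, 1].
#' @return integer `q`.
#' @export
choose_q <- function(eigenvalues, variance_fraction = 0.9) {
  if (variance_fraction <= 0 || variance_fraction > 1) {
    stop_value("variance_fraction must be in (0, 1]")
  }
  lam <- pmax(eigenvalues, 0)
  tot <- sum(lam)
  if (tot <= 0) stop_value("all-zero spectrum: no variance to retain")
  frac <- cumsum(lam) / tot
  q <- which(frac >= variance_fraction - 1e-12)[1L]
  if (variance_fraction == 1) q <- max(which(lam > 0))
  as.integer(q)
}

#' Row projections onto the leading eigenvectors
#'
#' Stacks the first `q` eigenvector columns into `A_q`; its rows `a_i` are
#' the projections of each voxel onto the retained component space — the
#' objects PFA clusters.
#'
#' @param decomposition a `dependency_eigen`.
#' @param q number of retained components (e.g. from [choose_q()]).
#' @return an object of class `projection_rows` with `rows` (n x q matrix),
#'   `q`, and `retained_variance`.
#' @export
projection_rows <- function(decomposition, q) {
  stopifnot(inherits(decomposition, "dependency_eigen"))
  n <- length(decomposition$eigenvalues)
  q <- as.integer(q)
  if (q < 1L || q > n) stop_value("q must be in 1..n")
  lam <- pmax(decomposition$eigenvalues, 0)
  structure(
    list(rows = decomposition$eigenvectors[, seq_len(q), drop = FALSE],
         q = q,
         retained_variance = sum(lam[seq_len(q)]) / sum(lam)),
    class = "projection_rows"
  )
}

#' Cosine distance between two vectors
#'
#' `1 - cos(u, v)`, in `[0, 2]`.
#'
#' @param u,v numeric vectors of equal length with nonzero norm.
#' @return scalar distance.
#' @export
cosine_distance <- function(u, v) {
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0) stop_value("cosine distance undefined for zero-norm vector")
  d <- 1 - sum(u * v) / (nu * nv)
  min(max(d, 0), 2)
}

# Cosine-distance matrix between rows of X and rows of C.
# Zero-norm rows of X are given distance 1 to every center (cosine 0), which
# sends them to the lowest center id under the tie-break.
cosine_dist_matrix <- function(X, C) {
  Xn <- normalize_rows(X)
  Cn <- normalize_rows(C)
  D <- 1 - Xn %*% t(Cn)
  pmin(pmax(D, 0), 2)
}

kmeans_objective <- function(X, centers, assignment) {
  D <- cosine_dist_matrix(X, centers)
  sum(D[cbind(seq_len(nrow(X)), assignment)])
}

#' Cosine k-means on projection rows
#'
#' Lloyd iterations under cosine distance: initial centers are `k` rows
#' drawn without replacement with the seeded generator; each row is assigned
#' to its nearest center (ties to the lowest center id); each center is
#' recomputed as the member mean renormalized to unit length; iteration stops
#' when the assignment is a fixed point or `max_iter` is reached. An emptied
#' cluster is repaired by moving in the row farthest from its own center.
#'
#' @param rows a `projection_rows` or a bare numeric matrix (rows = samples).
#' @param k number of clusters.
#' @param seed integer seed for center initialization.
#' @param max_iter iteration guard (default 300).
#' @return an object of class `cosine_kmeans` with `assignment` (1-based
#'   cluster ids), `centers` (k x q, unit rows), `n_iterations`, `objective`
#'   (total within-cluster cosine distance), `converged`, and `seed`.
#' @export
kmeans_cosine <- function(rows, k, seed = 1L, max_iter = 300L) {
  X <- if (inherits(rows, "projection_rows")) rows$rows else as.matrix(rows)
  n <- nrow(X)
  if (k <= 0L) stop_value("k must be positive")
  n_nonzero <- sum(row_norms(X) > 0)
  if (k > n_nonzero) {
    stop_value("k = ", k, " exceeds the ", n_nonzero,
               " rows with nonzero norm")
  }
  if (max_iter < 1L) stop_value("max_iter must be >= 1")
  init <- with_seed(seed, sample.int(n, k))
  centers <- normalize_rows(X[init, , drop = FALSE])
  assignment <- integer(n)
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    D <- cosine_dist_matrix(X, centers)
    new_assignment <- max.col(-D, ties.method = "first")
    # repair empty clusters: pull in the row farthest from its own center
    repeat {
      sizes <- tabulate(new_assignment, nbins = k)
      empty <- which(sizes == 0L)
      if (length(empty) == 0L) break
      d_own <- D[cbind(seq_len(n), new_assignment)]
      d_own[sizes[new_assignment] <= 1L] <- -Inf   # don't empty another cluster
      new_assignment[which.max(d_own)] <- empty[1L]
    }
    if (iter > 1L && all(new_assignment == assignment)) {
      converged <- TRUE
      assignment <- new_assignment
      break
    }
    assignment <- new_assignment
    for (j in seq_len(k)) {
      mu <- colMeans(X[assignment == j, , drop = FALSE])
      nrm <- sqrt(sum(mu * mu))
      if (nrm > 0) centers[j, ] <- mu / nrm
      # zero mean vector (antipodal members): keep the previous center
    }
    if (iter >= max_iter) break
  }
  structure(
    list(k = k, assignment = assignment, centers = centers,
         n_iterations = iter, objective = kmeans_objective(X, centers, assignment),
         converged = converged, seed = seed),
    class = "cosine_kmeans"
  )
}

#' Construct a selected-features object
#'
#' @param indices distinct 1-based voxel row indices, in selection order.
#' @param scores per-index selection scores.
#' @param method selector name.
#' @param category optional stimulus-category tag.
#' @return an object of class `selected_features`.
#' @export
selected_features <- function(indices, scores = rep(NA_real_, length(indices)),
                              method = "unknown", category = NULL) {
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop_value("selected indices must be distinct")
  if (length(scores) != length(indices)) {
    stop_value("scores must align with indices")
  }
  structure(list(indices = indices, scores = as.numeric(scores),
                 method = method, category = category),
            class = "selected_features")
}

#' @export
print.selected_features <- function(x, ...) {
  cat(sprintf("<selected_features> %d voxels by %s%s\n", length(x$indices),
              x$method,
              if (is.null(x$category)) "" else paste0(" [", x$category, "]")))
  invisible(x)
}

#' @export
length.selected_features <- function(x) length(x$indices)

#' One representative voxel per cluster
#'
#' For each cluster, retains the member whose projection row is closest (in
#' cosine distance) to the cluster center; ties go to the lowest voxel index.
#' Output is ordered by cluster id, so a k-cluster model yields exactly k
#' distinct voxels.
#'
#' @param model a `cosine_kmeans`.
#' @param rows the `projection_rows` (or matrix) the model was fit on.
#' @return a `selected_features`; scores are the (negated) cosine distances
#'   to the center, so higher is better.
#' @export
select_cluster_representatives <- function(model, rows) {
  X <- if (inherits(rows, "projection_rows")) rows$rows else as.matrix(rows)
  D <- cosine_dist_matrix(X, model$centers)
  idx <- integer(model$k)
  sc <- numeric(model$k)
  for (j in seq_len(model$k)) {
    members <- which(model$assignment == j)
    best <- members[which.min(D[members, j])]   # which.min takes first on ties
    idx[j] <- best
    sc[j] <- -D[best, j]
  }
  selected_features(idx, sc, method = "pfa")
}

#' Rank selected features by leading-eigenvector loading
#'
#' Scores voxel `i` by `|e_1[i]|`, the magnitude of its loading on the
#' eigenvector of the largest eigenvalue, and reorders the selection by
#' descending score (ties to the lowest index). Clusters made of pure noise
#' load weakly on the leading component, so their representatives sink to the
#' bottom; truncation to the requested budget is left to the caller.
#'
#' @param selected a `selected_features`.
#' @param decomposition a `dependency_eigen`.
#' @return the reordered `selected_features` with the new scores.
#' @export
rank_by_leading_eigenvector <- function(selected, decomposition) {
  stopifnot(inherits(selected, "selected_features"),
            inherits(decomposition, "dependency_eigen"))
  e1 <- decomposition$eigenvectors[, 1L]
  if (any(selected$indices < 1L) || any(selected$indices > length(e1))) {
    stop_value("selected index out of range")
  }
  sc <- abs(e1[selected$indices])
  ord <- order(-sc, selected$indices)
  selected_features(selected$indices[ord], sc[ord], method = selected$method,
                    category = selected$category)
}

#' Principal feature analysis voxel selection
#'
#' Full PFA pipeline: dependency matrix, eigendecomposition, component count
#' by retained variance, cosine k-means on the row projections (best of
#' `n_restarts` seeded restarts by within-cluster objective), one
#' representative per cluster, leading-eigenvector ranking, truncation to
#' `n_features`.
#'
#' The cluster count is `k = min(n, ceiling(oversample_factor * n_features))`;
#' oversampling gives the leading-eigenvector filter noise-cluster
#' representatives to discard, while `oversample_factor = 1` reproduces
#' unfiltered PFA.
#'
#' @param ts a `voxel_ts` or voxels x observations matrix.
#' @param n_features number of voxels to select.
#' @param mode dependency mode, `"correlation"` (default) or `"covariance"`.
#' @param variance_fraction retained-variance target for [choose_q()]
#'   (default 0.9).
#' @param oversample_factor cluster oversampling factor (default 1.2).
#' @param seed integer seed; restart seeds are derived from it.
#' @param max_iter per-restart Lloyd iteration cap.
#' @param n_restarts number of k-means restarts (default 10; 1 mirrors a
#'   single random initialization).
#' @return a `selected_features` with attribute `pfa_info` recording `q`,
#'   `retained_variance`, `k`, the winning restart's iterations and
#'   objective.
#' @export
pfa_select <- function(ts, n_features,
                       mode = c("correlation", "covariance"),
                       variance_fraction = 0.9, oversample_factor = 1.2,
                       seed = 1L, max_iter = 300L, n_restarts = 10L) {
  mode <- match.arg(mode)
  Y <- if (inherits(ts, "voxel_ts")) ts$values else as.matrix(ts)
  n <- nrow(Y)
  if (n_features < 1L || n_features > n) {
    stop_value("n_features must be in 1..n")
  }
  sigma <- compute_dependency_matrix(ts, mode = mode)
  dec <- eigendecompose(sigma)
  q <- choose_q(dec$eigenvalues, variance_fraction)
  pr <- projection_rows(dec, q)
  k <- min(n, as.integer(ceiling(oversample_factor * n_features)))
  seeds <- derive_seeds(seed, n_restarts)
  best <- NULL
  for (s in seeds) {
    fit <- kmeans_cosine(pr, k, seed = s, max_iter = max_iter)
    if (is.null(best) || fit$objective < best$objective - 1e-12) best <- fit
  }
  sel <- select_cluster_representatives(best, pr)
  sel <- rank_by_leading_eigenvector(sel, dec)
  out <- selected_features(sel$indices[seq_len(n_features)],
                           sel$scores[seq_len(n_features)], method = "pfa")
  attr(out, "pfa_info") <- list(q = q, retained_variance = pr$retained_variance,
                                k = k, n_iterations = best$n_iterations,
                                objective = best$objective)
  out
}
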