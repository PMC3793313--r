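# Shared fixture builders and independent oracles. Everything is generated
# in code; no binary fixtures on disk.

# small voxel_ts on a real 3-D grid
make_grid_ts <- function(n = 10L, L = 20L, shape = c(5L, 2L, 1L), seed = 1L) {
  set.seed(seed)
  voxel_time_series(matrix(rnorm(n * L), n, L),
                    voxel_index = arrayInd(seq_len(n), .dim = shape) - 1L,
                    grid_shape = shape)
}

# write a tiny NIfTI series + mask pair, return their paths
make_nifti_pair <- function(dir = tempdir(), shape = c(4L, 4L, 4L), L = 10L,
                            n_mask = 5L, seed = 1L) {
  set.seed(seed)
  series <- array(rnorm(prod(shape) * L), dim = c(shape, L))
  mask <- array(0, dim = shape)
  mask[sample.int(prod(shape), n_mask)] <- 1
  sp <- tempfile("series", dir, ".nii")
  mp <- tempfile("mask", dir, ".nii")
  write_nifti(series, sp, datatype = 64L)
  write_nifti(mask, mp, datatype = 2L)
  list(series = sp, mask = mp, series_arr = series, mask_arr = mask)
}

# brute-force sample covariance by the definitional double loop
oracle_cov <- function(Y) {
  n <- nrow(Y); L <- ncol(Y)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    mi <- mean(Y[i, ]); mj <- mean(Y[j, ])
    S[i, j] <- sum((Y[i, ] - mi) * (Y[j, ] - mj)) / (L - 1)
  }
  S
}

# exhaustive cosine k-means optimum: best objective over all assignments of
# n rows to k nonempty clusters, centers = renormalized member means
oracle_kmeans_objective <- function(X, k) {
  n <- nrow(X)
  stopifnot(n <= 8L, k <= 3L)
  Xn <- X / sqrt(rowSums(X^2))
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(k)), n)))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    a <- grid[g, ]
    if (length(unique(a)) < k) next
    S <- rowsum(X, a)                        # cluster sums = means * size
    nrm <- sqrt(rowSums(S^2))
    if (any(nrm == 0)) next
    Cn <- S / nrm                            # renormalized means
    obj <- sum(1 - rowSums(Xn * Cn[match(a, sort(unique(a))), , drop = FALSE]))
    if (obj < best) best <- obj
  }
  best
}

# exact Wilcoxon p by full 2^n sign enumeration (n <= 12)
oracle_wilcoxon_greater <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  count <- 0
  for (m in 0:(2^n - 1)) {
    signs <- bitwAnd(m, 2^(0:(n - 1))) > 0
    if (sum(r[signs]) >= W - 1e-9) count <- count + 1
  }
  count / 2^n
}

# small synthetic spec for fast tests (40 stimuli, short blocks)
small_spec <- function(...) {
  synthetic_spec(n_voxels = 48L, grid_shape = c(6L, 4L, 2L),
                 n_stimuli_per_category = 10L,
                 task_run_trials = c(14L, 14L, 12L),
                 block_observations = 5L, ...)
}
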