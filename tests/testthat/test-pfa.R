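test_that("dependency matrix matches the definitional double-loop oracle", {
  Y <- rbind(c(1, 2, 3, 4), c(4, 3, 2, 1), c(1, 1, 2, 2))
  S <- compute_dependency_matrix(Y, mode = "covariance")
  expect_equal(S, oracle_cov(Y), tolerance = 1e-12)
  # spot values by hand: var(row1) = 5/3, cov(1,2) = -5/3, cov(1,3) = 2/3
  expect_equal(S[1, 1], 5 / 3)
  expect_equal(S[1, 2], -5 / 3)
  expect_equal(S[1, 3], 2 / 3)
  # random matrices too
  for (seed in 1:3) {
    set.seed(seed)
    Y <- matrix(rnorm(5 * 8), 5, 8)
    expect_equal(compute_dependency_matrix(Y, "covariance"), oracle_cov(Y),
                 tolerance = 1e-12)
  }
})

test_that("correlation mode normalizes rows and rejects constants", {
  Y <- rbind(c(0, 1, 2, 3), c(0, 2, 4, 6))     # identical up to scale
  expect_equal(compute_dependency_matrix(Y, "correlation"),
               matrix(1, 2, 2), tolerance = 1e-12)
  Ybad <- rbind(c(0, 2), c(1, 1))
  expect_equal(compute_dependency_matrix(Ybad, "covariance"),
               rbind(c(2, 0), c(0, 0)), tolerance = 1e-12)
  expect_error(compute_dependency_matrix(Ybad, "correlation"), "row 2")
})

test_that("eigendecompose sorts, signs, and reconstructs", {
  d <- eigendecompose(diag(c(2, 1)))
  expect_equal(d$eigenvalues, c(2, 1))
  expect_equal(d$eigenvectors, diag(2))
  d <- eigendecompose(matrix(1, 2, 2))
  expect_equal(d$eigenvalues, c(2, 0))
  expect_equal(d$eigenvectors[, 1], c(1, 1) / sqrt(2))
  # degenerate spectrum still satisfies the reconstruction invariant
  d <- eigendecompose(diag(3))
  expect_equal(d$eigenvalues, c(1, 1, 1))
  recon <- d$eigenvectors %*% diag(d$eigenvalues) %*% t(d$eigenvectors)
  expect_lt(norm(recon - diag(3), "F"), 1e-8 * norm(diag(3), "F"))
  expect_error(eigendecompose(matrix(c(1, 2, 3, 4), 2, 2)), "symmetric")
})

test_that("reconstruction, orthonormality and sign convention hold on random input", {
  for (seed in 1:10) {
    set.seed(seed)
    M <- matrix(rnorm(36), 6, 6)
    S <- (M + t(M)) / 2
    d <- eigendecompose(S)
    A <- d$eigenvectors
    expect_lt(norm(A %*% diag(d$eigenvalues) %*% t(A) - S, "F"),
              1e-8 * norm(S, "F"))
    expect_equal(sqrt(colSums(A^2)), rep(1, 6), tolerance = 1e-9)
    expect_true(all(diff(d$eigenvalues) <= 1e-9))
    for (j in 1:6) expect_gte(A[which.max(abs(A[, j])), j], 0)
  }
})

test_that("choose_q implements the smallest-q variance rule", {
  expect_identical(choose_q(c(2, 1, 1), 0.5), 1L)
  expect_identical(choose_q(c(2, 1, 1), 0.9), 3L)
  expect_identical(choose_q(c(2, 1, 1, 0, 0), 1.0), 3L)
  expect_identical(choose_q(c(5, 3, 2), 0.8), 2L)
  expect_error(choose_q(c(0, 0)), "all-zero")
  expect_error(choose_q(c(1), 1.5), "variance_fraction")
})

test_that("cosine distance has the right geometry", {
  expect_equal(cosine_distance(c(1, 2), c(2, 4)), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 3)), 1)
  expect_equal(cosine_distance(c(1, 1), -c(2, 2)), 2)
  expect_error(cosine_distance(c(0, 0), c(1, 0)), "zero-norm")
})

test_that("projection rows expose A_q and retained variance", {
  S <- diag(c(4, 3, 2, 1))
  d <- eigendecompose(S)
  pr <- projection_rows(d, 2L)
  expect_identical(pr$q, 2L)
  expect_equal(pr$rows, d$eigenvectors[, 1:2])
  expect_equal(pr$retained_variance, 7 / 10)
  expect_error(projection_rows(d, 0L), "1..n")
})

test_that("kmeans_cosine separates exact directions for every seed", {
  rows <- rbind(c(1, 0), c(1, 0), c(0, 1))
  for (seed in 1:10) {
    fit <- kmeans_cosine(rows, 2, seed = seed)
    expect_identical(fit$assignment[1], fit$assignment[2])
    expect_false(fit$assignment[1] == fit$assignment[3])
    expect_equal(fit$objective, 0, tolerance = 1e-12)
  }
  # all identical rows, k = 1: converges immediately to the normalized row
  rows <- matrix(rep(c(3, 4), 5), 5, 2, byrow = TRUE)
  fit <- kmeans_cosine(rows, 1, seed = 1)
  expect_equal(as.vector(fit$centers), c(0.6, 0.8))
  expect_true(fit$converged)
  expect_error(kmeans_cosine(rows, 0), "positive")
  expect_error(kmeans_cosine(rows, 6), "exceeds")
})

test_that("kmeans_cosine recovers the enumerated optimum on the angle fixture", {
  ang <- c(0, 5, 10, 80, 85, 90) * pi / 180
  rows <- cbind(cos(ang), sin(ang))
  best_obj <- oracle_kmeans_objective(rows, 2)
  fit <- kmeans_cosine(rows, 2, seed = 4)
  expect_identical(fit$assignment[1:3], rep(fit$assignment[1], 3L))
  expect_identical(fit$assignment[4:6], rep(fit$assignment[4], 3L))
  expect_equal(fit$objective, best_obj, tolerance = 1e-9)
})

test_that("cluster centers reproduce from their members", {
  set.seed(2)
  rows <- matrix(rnorm(30), 10, 3)
  fit <- kmeans_cosine(rows, 3, seed = 7)
  for (j in 1:3) {
    mu <- colMeans(rows[fit$assignment == j, , drop = FALSE])
    mu <- mu / sqrt(sum(mu^2))
    expect_equal(as.vector(fit$centers[j, ]), mu, tolerance = 1e-9)
  }
  expect_identical(sort(unique(fit$assignment)), 1:3)  # no empty cluster
})

test_that("representatives pick the member closest to its center", {
  # two clusters, the second containing a clearly closer member
  rows <- rbind(c(1, 0), c(0.9, 0.1), c(0, 1))
  fit <- kmeans_cosine(rows, 2, seed = 1)
  sel <- select_cluster_representatives(fit, rows)
  expect_identical(length(sel$indices), 2L)
  expect_false(anyDuplicated(sel$indices) > 0)
  # oracle: compute both cosine distances in the {1,2} cluster explicitly
  j <- fit$assignment[1]
  mu <- fit$centers[j, ]
  d1 <- cosine_distance(rows[1, ], mu)
  d2 <- cosine_distance(rows[2, ], mu)
  expect_identical(sel$indices[j], if (d1 <= d2) 1L else 2L)
  # duplicate rows: tie broken by lowest index
  rows2 <- rbind(c(1, 0), c(1, 0), c(0, 1))
  fit2 <- kmeans_cosine(rows2, 2, seed = 1)
  sel2 <- select_cluster_representatives(fit2, rows2)
  expect_true(1L %in% sel2$indices)
  expect_false(2L %in% sel2$indices)
})

test_that("leading-eigenvector ranking orders by |loading| with index ties", {
  dec <- structure(list(sigma = diag(3), eigenvalues = c(2, 1, 0.5),
                        eigenvectors = cbind(c(0.9, 0.1, 0.4),
                                             c(0, 1, 0), c(0, 0, 1))),
                   class = "dependency_eigen")
  sel <- selected_features(c(1L, 2L, 3L))
  out <- rank_by_leading_eigenvector(sel, dec)
  expect_identical(out$indices, c(1L, 3L, 2L))
  expect_equal(out$scores, c(0.9, 0.4, 0.1))
  # negative loadings score by magnitude
  dec$eigenvectors[, 1] <- c(-0.8, 0.2, 0.1)
  out <- rank_by_leading_eigenvector(selected_features(1:2), dec)
  expect_identical(out$indices, c(1L, 2L))
  # equal loadings fall back to index order
  dec$eigenvectors[, 1] <- c(0.5, 0.5, 0.5)
  out <- rank_by_leading_eigenvector(selected_features(c(3L, 1L, 2L)), dec)
  expect_identical(out$indices, 1:3)
})

test_that("pfa_select keeps one representative per planted signal group", {
  # 3 orthogonal signal groups with exact duplicates; correlation rows
  # coincide within groups, so k = 3 must pick one per group
  L <- 40L
  set.seed(5)
  base <- rbind(rep(c(1, -1), L / 2),
                rep(c(1, 1, -1, -1), L / 4),
                rep(c(1, 1, 1, 1, -1, -1, -1, -1), L / 8))
  Y <- base[c(1, 1, 2, 2, 3, 3), ] + 0   # duplicate each source exactly
  Y <- Y + matrix(0, 6, L)
  sel <- pfa_select(Y, 3, oversample_factor = 1.0, seed = 2)
  groups <- list(1:2, 3:4, 5:6)
  hits <- vapply(groups, function(g) sum(sel$indices %in% g), 1L)
  expect_identical(hits, rep(1L, 3))
})

test_that("pfa_select is deterministic and saturates", {
  set.seed(11)
  Y <- matrix(rnorm(12 * 30), 12, 30)
  s1 <- pfa_select(Y, 5, seed = 42)
  s2 <- pfa_select(Y, 5, seed = 42)
  expect_identical(s1$indices, s2$indices)
  expect_identical(sort(pfa_select(Y, 12, seed = 1)$indices), 1:12)
})

test_that("the sign convention neutralizes eigenvector sign ambiguity", {
  # an eigensolver may return any column signs; after the convention the
  # projection rows, and hence everything downstream, are identical
  set.seed(3)
  M <- matrix(rnorm(49), 7, 7)
  S <- crossprod(M)
  d <- eigendecompose(S)
  flipped <- d$eigenvectors %*% diag(c(-1, 1, -1, 1, -1, 1, -1))
  # re-apply the convention to the flipped basis
  for (j in seq_len(ncol(flipped))) {
    i <- which.max(abs(flipped[, j]))
    if (flipped[i, j] < 0) flipped[, j] <- -flipped[, j]
  }
  expect_equal(flipped, d$eigenvectors, tolerance = 1e-12)
})

test_that("pfa_select is permutation-equivariant on separated structure", {
  # near-duplicate pairs of three orthogonal sources: a unique, well
  # separated optimum, so the multi-restart best is the same optimum for
  # both row orders and selection maps through the permutation
  L <- 48L
  base <- rbind(rep(c(1, -1), L / 2),
                rep(c(1, 1, -1, -1), L / 4),
                rep(c(1, 1, 1, 1, -1, -1, -1, -1), L / 8))
  set.seed(21)
  Y <- base[rep(1:3, each = 2), ] + matrix(rnorm(6 * L, sd = 0.05), 6, L)
  s <- pfa_select(Y, 3, oversample_factor = 1.0, seed = 9)
  perm <- c(5L, 3L, 6L, 1L, 4L, 2L)
  sp <- pfa_select(Y[perm, ], 3, oversample_factor = 1.0, seed = 9)
  expect_setequal(perm[sp$indices], s$indices)
})
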