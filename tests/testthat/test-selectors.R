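make_block_ts <- function(values, task = 1:5, ctrl = 6:10, cat = "face") {
  L <- ncol(values)
  ts <- voxel_time_series(values)
  design <- design_table(run = c(1, 1), onset = c(min(task), min(ctrl)),
                         duration = c(length(task), length(ctrl)),
                         condition = c(cat, "control"))
  list(ts = ts, design = design)
}

test_that("tstat_scores matches the pooled two-sample formula", {
  # hand-computed: task (3,4,5,4) vs control (1,2,1,2) -> t = 5
  v <- rbind(c(3, 4, 5, 4, 1, 2, 1, 2),
             c(1, 2, 3, 1, 1, 2, 3, 1))   # identical groups -> t = 0
  fx <- make_block_ts(v, task = 1:4, ctrl = 5:8)
  sm <- tstat_scores(fx$ts, fx$design, "face", lag_observations = 0L)
  expect_equal(sm$t[1], 5)
  expect_equal(sm$t[2], 0)
  expect_equal(sm$scores, abs(sm$t))
  # oracle: base R pooled-variance t.test
  set.seed(4)
  v2 <- matrix(rnorm(3 * 8), 3, 8)
  fx2 <- make_block_ts(v2, task = 1:4, ctrl = 5:8)
  sm2 <- tstat_scores(fx2$ts, fx2$design, "face", lag_observations = 0L)
  for (i in 1:3) {
    expect_equal(sm2$t[i],
                 t.test(v2[i, 1:4], v2[i, 5:8], var.equal = TRUE)$statistic[[1]],
                 tolerance = 1e-12)
  }
})

test_that("label lag rewards a hemodynamically delayed response", {
  # response is the boxcar shifted by exactly 2 observations
  box <- rep(c(1, 0), each = 10)
  resp <- c(0, 0, box[1:18])
  set.seed(7)
  v <- rbind(resp * 3 + rnorm(20, sd = 0.1))
  ts <- voxel_time_series(rbind(v, rnorm(20)))
  design <- design_table(run = c(1, 1), onset = c(1, 11), duration = c(10, 8),
                         condition = c("face", "control"))
  s0 <- tstat_scores(ts, design, "face", lag_observations = 0L)
  s2 <- tstat_scores(ts, design, "face", lag_observations = 2L)
  expect_gt(s2$scores[1], s0$scores[1])
})

test_that("constant voxels score zero with a warning", {
  v <- rbind(rep(1, 10), rnorm(10))
  fx <- make_block_ts(v)
  expect_warning(sm <- tstat_scores(fx$ts, fx$design, "face", 0L),
                 "constant voxel")
  expect_equal(sm$scores[1], 0)
})

test_that("sphere offsets match exhaustive lattice enumeration", {
  counts <- vapply(0:4, function(r) {
    brute <- 0L
    for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
      if (dx^2 + dy^2 + dz^2 <= r^2) brute <- brute + 1L
    }
    off <- sphere_offsets(r)
    expect_identical(nrow(off), brute)
    brute
  }, 1L)
  expect_identical(counts[3], 33L)      # the canonical two-voxel radius
  off <- sphere_offsets(2)
  expect_true(any(rowSums(abs(off)) == 0))             # contains the origin
  expect_identical(nrow(unique(rbind(off, -off))), nrow(off))  # negation-closed
  expect_error(sphere_offsets(-1), "nonnegative")
})

test_that("searchlight averages |t| over the in-mask truncated sphere", {
  # 5x2x1 grid, all voxels in the mask
  ts <- make_grid_ts(n = 10L, L = 12L, shape = c(5L, 2L, 1L))
  const <- structure(list(scores = rep(3, 10), method = "tstat",
                          higher_is_better = TRUE), class = "score_map")
  out <- searchlight_scores(const, ts, radius = 2)
  expect_equal(out$scores, rep(3, 10))          # averaging constancy
  # radius 0 is the identity on |t|
  tm <- structure(list(scores = abs(rnorm(10)), method = "tstat",
                       higher_is_better = TRUE), class = "score_map")
  expect_equal(searchlight_scores(tm, ts, 0)$scores, tm$scores)
  # single nonzero t: each voxel's score = t / |in-mask sphere| when the hot
  # voxel is inside its sphere, else 0 — enumerate membership by brute force
  hot <- 3L
  tm1 <- structure(list(scores = c(0, 0, 5, rep(0, 7)), method = "tstat",
                        higher_is_better = TRUE), class = "score_map")
  out1 <- searchlight_scores(tm1, ts, 2)
  coords <- ts$voxel_index
  for (i in 1:10) {
    inside <- 0L; has_hot <- FALSE
    for (j in 1:10) {
      if (sum((coords[j, ] - coords[i, ])^2) <= 4) {
        inside <- inside + 1L
        if (j == hot) has_hot <- TRUE
      }
    }
    expect_equal(out1$scores[i], if (has_hot) 5 / inside else 0)
  }
})

test_that("top_n_select ranks, breaks ties by index, and is monotone", {
  expect_identical(top_n_select(c(0.1, 0.9, 0.5), 2)$indices, c(2L, 3L))
  expect_identical(top_n_select(rep(1, 4), 2)$indices, c(1L, 2L))
  expect_identical(sort(top_n_select(rnorm(6), 6)$indices), 1:6)
  sc <- rnorm(30)
  prev <- integer(0)
  for (n in c(3, 10, 22, 30)) {
    cur <- top_n_select(sc, n)$indices
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  expect_error(top_n_select(1:3, 0), "positive")
  expect_error(top_n_select(1:3, 4), "exceeds")
})

test_that("per-category union deduplicates and caps by max cross-category score", {
  spec <- small_spec(seed = 5)
  loc <- generate_localizer_session(spec, seed = 6)
  ts <- detrend_linear(loc$ts)
  sel <- per_category_union(ts, loc$design, spec$categories, method = "tstat",
                            per_category_budget = 4)
  expect_false(anyDuplicated(sel$indices) > 0)
  expect_lte(length(sel$indices), 16L)
  prov <- attr(sel, "provenance")
  expect_setequal(unique(prov$category), spec$categories)
  # idempotence: a single category's union is just its subset
  sel1 <- per_category_union(ts, loc$design, spec$categories[1],
                             method = "tstat", per_category_budget = 4)
  direct <- top_n_select(tstat_scores(ts, loc$design, spec$categories[1]), 4)
  expect_setequal(sel1$indices, direct$indices)
  # total budget caps by maximum cross-category score
  capped <- per_category_union(ts, loc$design, spec$categories,
                               method = "tstat", per_category_budget = 4,
                               total_budget = 5)
  expect_identical(length(capped$indices), 5L)
  best <- aggregate(score ~ voxel, data = prov, FUN = max)
  keep <- best$voxel[order(-best$score, best$voxel)][1:5]
  expect_setequal(capped$indices, keep)
})

test_that("union of disjoint planted category sets is the concatenation", {
  # abstract union semantics: subsets {1,2} and {2,3} -> {1,2,3} is covered
  # by the dedup test; here disjoint per-category t-stat winners add up
  spec <- small_spec(seed = 8, strong_fraction = 0.1, weak_fraction = 0.1,
                     redundancy_copies = 0L)
  loc <- generate_localizer_session(spec, seed = 9)
  ts <- detrend_linear(loc$ts)
  tr <- loc$truth
  sel <- per_category_union(ts, loc$design, spec$categories, method = "tstat",
                            per_category_budget = 1)
  # each category's single best voxel is one of its planted strong voxels,
  # and they are disjoint across categories, so the union has size 4
  expect_identical(length(sel$indices), 4L)
  expect_true(all(sel$indices %in% tr$strong))
})

test_that("tstat top-N recovers strong voxels among pure noise", {
  # 6 blocks x 15 observations, d = 1.5: recall >= 0.9 over 20 seeds
  spec <- synthetic_spec(n_voxels = 96L, grid_shape = c(6L, 4L, 4L),
                         blocks_per_run = 6L, block_observations = 15L,
                         n_stimuli_per_category = 6L,
                         task_run_trials = c(8L, 8L, 8L),
                         redundancy_copies = 0L, seed = 2)
  recalls <- vapply(1:20, function(s) {
    spec_s <- spec; spec_s$seed <- s + 1000L
    loc <- generate_localizer_run(spec_s, "animal", seed = s)
    ts <- detrend_linear(loc$ts)
    planted <- loc$truth$strong[
      loc$truth$category_of_voxel[loc$truth$strong] == "animal"]
    sel <- top_n_select(tstat_scores(ts, loc$design, "animal"),
                        length(planted))
    mean(planted %in% sel$indices)
  }, 1)
  expect_gte(mean(recalls), 0.9)
})

test_that("searchlight boosts voxels adjacent to an active clump", {
  # strong sources sit in contiguous clumps; their in-mask neighbours score
  # higher than isolated noise voxels far from any clump
  spec <- synthetic_spec(seed = 3, redundancy_copies = 0L)
  loc <- generate_localizer_run(spec, "animal", seed = 31)
  ts <- detrend_linear(loc$ts)
  tr <- loc$truth
  planted <- tr$strong[tr$category_of_voxel[tr$strong] == "animal"]
  sl <- searchlight_scores(tstat_scores(ts, loc$design, "animal"), ts, 2)
  coords <- ts$voxel_index
  d2 <- function(i, j) sum((coords[i, ] - coords[j, ])^2)
  near <- setdiff(which(vapply(seq_len(nrow(coords)), function(i)
    any(vapply(planted, function(p) d2(i, p) <= 4, TRUE)), TRUE)),
    c(planted, tr$weak, unlist(tr$duplicate_groups)))
  informative <- unique(c(tr$strong, tr$weak, unlist(tr$duplicate_groups)))
  far <- which(vapply(seq_len(nrow(coords)), function(i)
    all(vapply(informative, function(p) d2(i, p) > 4, TRUE)), TRUE))
  expect_gt(mean(sl$scores[near]), mean(sl$scores[far]))
})
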