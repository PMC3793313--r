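# Comparator selectors: univariate t-statistic ranking and spherical
# searchlight average-absolute-t scoring, plus top-N selection and the
# per-category / union protocol shared by all methods.

#' Per-voxel two-sample t scores for a localizer contrast
#'
#' For each voxel, computes the pooled-variance two-sample t statistic
#' between task-labeled and control-labeled observations of the block
#' design; the score is `|t|`. Labels are shifted forward by
#' `lag_observations` to crudely account for hemodynamic delay (default 1
#' observation, about 2 s at TR 2 s). A voxel with zero pooled variance
#' carries no contrast and scores 0 (with a warning).
#'
#' @param ts a `voxel_ts`.
#' @param design a `design_table` with task blocks labeled by category and
#'   control blocks labeled `"control"`.
#' @param category the task condition label to contrast against control.
#' @param lag_observations forward label shift in observations.
#' @return an object of class `score_map`: `scores` (length n, `|t|`),
#'   `t` (signed t), `method`, `higher_is_better`.
#' @export
tstat_scores <- function(ts, design, category, lag_observations = 1L) {
  stopifnot(inherits(ts, "voxel_ts"))
  labels <- design_labels(ts, design, lag = lag_observations)
  task <- which(labels == category)
  ctrl <- which(labels == "control")
  if (length(task) < 2L || length(ctrl) < 2L) {
    stop_value("need >= 2 task and >= 2 control observations after lag shift")
  }
  Y1 <- ts$values[, task, drop = FALSE]
  Y0 <- ts$values[, ctrl, drop = FALSE]
  n1 <- length(task); n0 <- length(ctrl)
  m1 <- rowMeans(Y1); m0 <- rowMeans(Y0)
  ss1 <- rowSums((Y1 - m1)^2)
  ss0 <- rowSums((Y0 - m0)^2)
  sp2 <- (ss1 + ss0) / (n1 + n0 - 2L)
  tval <- numeric(nrow(Y1))
  nz <- sp2 > 0
  tval[nz] <- (m1[nz] - m0[nz]) / sqrt(sp2[nz] * (1 / n1 + 1 / n0))
  if (any(!nz)) {
    warning(sum(!nz), " constant voxel(s) scored 0 (zero pooled variance)",
            call. = FALSE)
  }
  structure(list(scores = abs(tval), t = tval, method = "tstat",
                 higher_is_better = TRUE),
            class = "score_map")
}

#' @export
print.score_map <- function(x, ...) {
  cat(sprintf("<score_map> %s over %d voxels, range [%.3g, %.3g]\n",
              x$method, length(x$scores), min(x$scores), max(x$scores)))
  invisible(x)
}

#' Integer offsets of a spherical searchlight
#'
#' All integer displacements `(dx, dy, dz)` with
#' `dx^2 + dy^2 + dz^2 <= radius^2`, in deterministic lexicographic order
#' (dz slowest, dx fastest). Radius 2 yields the canonical 33-voxel sphere.
#'
#' @param radius nonnegative radius in voxel units (integer or half-integer).
#' @return integer matrix with columns `dx`, `dy`, `dz`; contains the origin
#'   and is closed under negation.
#' @export
sphere_offsets <- function(radius) {
  if (length(radius) != 1L || !is.finite(radius) || radius < 0) {
    stop_value("radius must be a nonnegative number")
  }
  r <- floor(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  keep <- g$dx^2 + g$dy^2 + g$dz^2 <= radius^2 + 1e-9
  g <- g[keep, , drop = FALSE]
  g <- g[order(g$dz, g$dy, g$dx), , drop = FALSE]
  m <- as.matrix(g)
  dimnames(m) <- list(NULL, c("dx", "dy", "dz"))
  storage.mode(m) <- "integer"
  m
}

#' Spherical-searchlight scores from a t-map
#'
#' Assigns each voxel the mean of `|t|` over the spherical neighborhood
#' centered on it; neighbors outside the volume or outside the mask are
#' excluded from both numerator and denominator (the sphere is truncated at
#' the mask boundary). With radius 0 this is exactly `|t|`.
#'
#' @param tmap a `score_map` (e.g. from [tstat_scores()]) aligned with `ts`.
#' @param ts the `voxel_ts` providing voxel coordinates and grid shape.
#' @param radius sphere radius in voxels (default 2, the 33-voxel sphere).
#' @return a `score_map` with method `"searchlight"`.
#' @export
searchlight_scores <- function(tmap, ts, radius = 2) {
  stopifnot(inherits(tmap, "score_map"), inherits(ts, "voxel_ts"))
  n <- nrow(ts$values)
  if (length(tmap$scores) != n) stop_value("tmap not aligned with ts")
  off <- sphere_offsets(radius)
  shape <- ts$grid_shape
  lookup <- array(NA_integer_, dim = shape)
  lin <- ts$voxel_index[, 1L] + 1L + ts$voxel_index[, 2L] * shape[1L] +
    ts$voxel_index[, 3L] * shape[1L] * shape[2L]
  lookup[lin] <- seq_len(n)
  absval <- abs(tmap$scores)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- sweep(off, 2L, ts$voxel_index[i, ], "+")
    ok <- nb[, 1L] >= 0L & nb[, 1L] < shape[1L] &
          nb[, 2L] >= 0L & nb[, 2L] < shape[2L] &
          nb[, 3L] >= 0L & nb[, 3L] < shape[3L]
    nb <- nb[ok, , drop = FALSE]
    rows <- lookup[nb[, 1L] + 1L + nb[, 2L] * shape[1L] +
                     nb[, 3L] * shape[1L] * shape[2L]]
    rows <- rows[!is.na(rows)]
    out[i] <- mean(absval[rows])   # sphere always contains its own center
  }
  structure(list(scores = out, method = "searchlight",
                 higher_is_better = TRUE),
            class = "score_map")
}

#' Select the top-N voxels of a score map
#'
#' Keeps the `n` highest-scoring voxel indices; ties at the cutoff are broken
#' by lowest index. Output is ordered by descending score. Increasing `n`
#' always yields a superset.
#'
#' @param scores a `score_map` or bare numeric vector.
#' @param n number of voxels to keep.
#' @param method selector name recorded in the output.
#' @return a `selected_features`.
#' @export
top_n_select <- function(scores, n, method = NULL) {
  sc <- if (inherits(scores, "score_map")) scores$scores else as.numeric(scores)
  if (is.null(method)) {
    method <- if (inherits(scores, "score_map")) scores$method else "topn"
  }
  if (n <= 0L) stop_value("n must be positive")
  if (n > length(sc)) stop_value("n exceeds the number of voxels")
  ord <- order(-sc, seq_along(sc))[seq_len(n)]
  selected_features(ord, sc[ord], method = method)
}

#' Per-category selection with union
#'
#' Runs a selector independently for each stimulus category (each category's
#' localizer contrast) and takes the union of the per-category subsets. If
#' the union exceeds `total_budget`, the top `total_budget` voxels by maximum
#' cross-category score are kept. Per-voxel provenance (which categories
#' selected it, with what score) is recorded.
#'
#' @param ts a `voxel_ts` of the localizer data.
#' @param design the localizer `design_table` (task blocks labeled by
#'   category, control blocks `"control"`). For `method = "pfa"` the design
#'   is used only to pick each category's run(s).
#' @param categories character vector of category labels.
#' @param method `"pfa"`, `"tstat"` or `"searchlight"`.
#' @param per_category_budget voxels to select per category.
#' @param total_budget optional cap on the union size.
#' @param lag_observations label lag for the t contrast.
#' @param radius searchlight radius.
#' @param ... further arguments passed to [pfa_select()].
#' @return a `selected_features` with method `"<method>+union"` and an
#'   attribute `provenance`: a data.frame of (voxel, category, score).
#' @export
per_category_union <- function(ts, design, categories,
                               method = c("pfa", "tstat", "searchlight"),
                               per_category_budget, total_budget = NULL,
                               lag_observations = 1L, radius = 2, ...) {
  method <- match.arg(method)
  if (per_category_budget <= 0L) stop_value("per_category_budget must be positive")
  prov <- list()
  for (cat in categories) {
    sel <- switch(
      method,
      tstat = top_n_select(
        tstat_scores(ts, design, cat, lag_observations), per_category_budget),
      searchlight = top_n_select(
        searchlight_scores(tstat_scores(ts, design, cat, lag_observations),
                           ts, radius), per_category_budget),
      pfa = {
        cat_ts <- subset_runs(ts, design$run[design$condition == cat])
        pfa_select(cat_ts, per_category_budget, ...)
      })
    prov[[cat]] <- data.frame(voxel = sel$indices, category = cat,
                              score = sel$scores, stringsAsFactors = FALSE)
  }
  prov <- do.call(rbind, prov)
  rownames(prov) <- NULL
  best <- stats::aggregate(score ~ voxel, data = prov, FUN = max)
  best <- best[order(-best$score, best$voxel), , drop = FALSE]
  if (!is.null(total_budget) && nrow(best) > total_budget) {
    best <- best[seq_len(total_budget), , drop = FALSE]
  }
  out <- selected_features(best$voxel, best$score,
                           method = paste0(method, "+union"))
  attr(out, "provenance") <- prov
  out
}

#' Restrict a voxel time series to a subset of runs
#'
#' @param ts a `voxel_ts`.
#' @param runs run ids to keep.
#' @return a `voxel_ts` containing only those runs' observations.
#' @export
subset_runs <- function(ts, runs) {
  cols <- which(ts$run_id %in% runs)
  if (length(cols) < 2L) stop_value("selected runs contain < 2 observations")
  voxel_time_series(ts$values[, cols, drop = FALSE], ts$voxel_index,
                    ts$grid_shape, ts$run_id[cols],
                    if (is.null(ts$condition)) NULL else ts$condition[cols],
                    ts$tr_seconds)
}
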