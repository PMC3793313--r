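# Voxel x observation data model: flattening masked 4-D series into matrices,
# design tables, and per-run linear detrending.

#' Construct a voxel time-series object
#'
#' The unit all selectors consume: an `n` voxels x `L` observations matrix
#' `Y` together with the 3-D coordinate of every voxel row, per-observation
#' run labels and (optionally) condition labels.
#'
#' Voxel rows are ordered by ascending linearized coordinate with x varying
#' fastest — the order in which a masked volume unravels — so row order is
#' deterministic given the mask and downstream tie-breaking is reproducible.
#' Coordinates are 0-based voxel indices; millimetre space is out of scope.
#'
#' @param values numeric matrix, `n` voxels x `L` observations. Non-finite
#'   entries are rejected rather than imputed.
#' @param voxel_index integer matrix `n` x 3 of 0-based voxel coordinates, or
#'   `NULL` for matrix-only workflows (a degenerate `n` x 1 x 1 grid is used).
#' @param grid_shape integer length-3 volume shape the coordinates live in.
#' @param run_id integer vector of length `L` assigning each observation to a
#'   run; defaults to a single run.
#' @param condition optional character vector of length `L` of per-observation
#'   labels (task category, `"control"`, `"blank"`, or `""` for unlabeled).
#' @param tr_seconds repetition time in seconds (default 2, the acquisition
#'   TR the design defaults assume).
#' @return an object of class `voxel_ts`.
#' @export
voxel_time_series <- function(values, voxel_index = NULL, grid_shape = NULL,
                              run_id = NULL, condition = NULL,
                              tr_seconds = 2) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  assert_finite_matrix(values, "values")
  n <- nrow(values)
  L <- ncol(values)
  if (n < 1L || L < 2L) stop_value("need n >= 1 voxels and L >= 2 observations")
  if (is.null(voxel_index)) {
    voxel_index <- cbind(seq_len(n) - 1L, 0L, 0L)
    grid_shape <- c(n, 1L, 1L)
  }
  voxel_index <- matrix(as.integer(voxel_index), ncol = 3L)
  if (nrow(voxel_index) != n) stop_value("voxel_index must have one row per voxel")
  if (anyDuplicated(voxel_index)) stop_value("voxel_index entries must be unique")
  if (is.null(grid_shape)) grid_shape <- apply(voxel_index, 2L, max) + 1L
  grid_shape <- as.integer(grid_shape)
  if (any(voxel_index < 0L) ||
      any(voxel_index >= matrix(grid_shape, n, 3L, byrow = TRUE))) {
    stop_value("voxel_index out of grid bounds")
  }
  if (is.null(run_id)) run_id <- rep(1L, L)
  run_id <- as.integer(run_id)
  if (length(run_id) != L) stop_value("run_id must have one entry per observation")
  if (!is.null(condition)) {
    condition <- as.character(condition)
    if (length(condition) != L) {
      stop_value("condition must have one entry per observation")
    }
  }
  structure(
    list(values = values, voxel_index = voxel_index,
         grid_shape = grid_shape, run_id = run_id, condition = condition,
         tr_seconds = tr_seconds),
    class = "voxel_ts"
  )
}

#' @export
print.voxel_ts <- function(x, ...) {
  cat(sprintf("<voxel_ts> %d voxels x %d observations, %d run(s), grid %s\n",
              nrow(x$values), ncol(x$values), length(unique(x$run_id)),
              paste(x$grid_shape, collapse = "x")))
  invisible(x)
}

#' @export
dim.voxel_ts <- function(x) dim(x$values)

mask_linear_indices <- function(mask) {
  idx <- which(mask != 0)
  if (length(idx) == 0L) stop_value("mask is empty (no nonzero voxels)")
  idx
}

#' Read a 4-D volume series restricted to a mask
#'
#' Flattens a 4-D NIfTI series to a voxel x observation matrix, one row per
#' nonzero mask voxel, rows in ascending linearized-coordinate order
#' (x fastest). Flatten and [unflatten_to_volume()] are mutually inverse on
#' the masked voxels.
#'
#' @param series_path path to a 4-D NIfTI-1 file.
#' @param mask_path path to a 3-D NIfTI-1 mask on the same grid; any nonzero
#'   value marks an in-mask voxel.
#' @param run_id,condition,tr_seconds forwarded to [voxel_time_series()].
#' @return a `voxel_ts`.
#' @export
read_volume_series <- function(series_path, mask_path, run_id = NULL,
                               condition = NULL, tr_seconds = 2) {
  series <- read_nifti(series_path)
  mask <- read_nifti(mask_path)
  if (length(dim(series)) != 4L) stop_value("series must be 4-D")
  if (length(dim(mask)) != 3L) stop_value("mask must be 3-D")
  if (!identical(dim(series)[1:3], dim(mask))) {
    stop_value("grid mismatch: series ", paste(dim(series)[1:3], collapse = "x"),
               " vs mask ", paste(dim(mask), collapse = "x"))
  }
  lin <- mask_linear_indices(mask)
  shape <- dim(mask)
  L <- dim(series)[4L]
  flat <- matrix(series, nrow = prod(shape), ncol = L)
  values <- flat[lin, , drop = FALSE]
  coords <- arrayInd(lin, .dim = shape) - 1L
  voxel_time_series(values, voxel_index = coords, grid_shape = shape,
                    run_id = run_id, condition = condition,
                    tr_seconds = tr_seconds)
}

#' Read a delimited voxel x observation matrix
#'
#' Plain-text alternative to NIfTI input: voxels in rows, observations in
#' columns, no header or row names.
#'
#' @param path path to a delimited text file.
#' @param sep field separator (default tab).
#' @inheritParams read_volume_series
#' @return a `voxel_ts` on a degenerate `n` x 1 x 1 grid.
#' @export
read_matrix_series <- function(path, sep = "\t", run_id = NULL,
                               condition = NULL, tr_seconds = 2) {
  values <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  dimnames(values) <- NULL
  voxel_time_series(values, run_id = run_id, condition = condition,
                    tr_seconds = tr_seconds)
}

#' Scatter per-voxel values back into a volume
#'
#' @param x numeric vector with one entry per voxel row of `ts`.
#' @param ts a `voxel_ts`.
#' @param fill value for out-of-mask voxels.
#' @return a 3-D array of shape `ts$grid_shape`.
#' @export
unflatten_to_volume <- function(x, ts, fill = 0) {
  stopifnot(length(x) == nrow(ts$values))
  vol <- array(fill, dim = ts$grid_shape)
  lin <- ts$voxel_index[, 1L] + 1L +
    ts$voxel_index[, 2L] * ts$grid_shape[1L] +
    ts$voxel_index[, 3L] * ts$grid_shape[1L] * ts$grid_shape[2L]
  vol[lin] <- x
  vol
}

#' Write a binary mask of selected voxels
#'
#' Produces a 3-D volume with 1 at each selected voxel and 0 elsewhere, with
#' geometry copied from a reference mask, so selections can be overlaid on
#' functional maps.
#'
#' @param selection a `selected_features` object (or bare integer vector of
#'   1-based voxel row indices).
#' @param reference_mask_path path to the mask the rows were flattened with.
#' @param out_path output `.nii` / `.nii.gz` path.
#' @return `out_path`, invisibly.
#' @export
write_selection_mask <- function(selection, reference_mask_path, out_path) {
  idx <- if (inherits(selection, "selected_features")) selection$indices else
    as.integer(selection)
  mask <- read_nifti(reference_mask_path)
  lin <- mask_linear_indices(mask)
  if (length(idx) > 0L && (min(idx) < 1L || max(idx) > length(lin))) {
    stop_value("selection index outside the reference mask (n = ",
               length(lin), ")")
  }
  out <- array(0, dim = dim(mask))
  out[lin[idx]] <- 1
  attr(out, "nifti_header") <- attr(mask, "nifti_header")
  write_nifti(out, out_path, datatype = 2L)
  invisible(out_path)
}

# ---- design tables ---------------------------------------------------------

#' Construct / validate a design table
#'
#' A design table encodes the block or trial structure of each run as rows of
#' `(run, onset, duration, condition)`. `onset` is the 1-based observation
#' index within the run; `duration` is in observations. Intervals within a
#' run must not overlap.
#'
#' @param run integer run ids.
#' @param onset 1-based onset observation index within the run.
#' @param duration interval length in observations.
#' @param condition character condition label per interval.
#' @return a `data.frame` of class `design_table`.
#' @export
design_table <- function(run, onset, duration, condition) {
  d <- data.frame(run = as.integer(run), onset = as.integer(onset),
                  duration = as.integer(duration),
                  condition = as.character(condition),
                  stringsAsFactors = FALSE)
  if (any(d$onset < 1L) || any(d$duration < 1L)) {
    stop_value("onsets must be >= 1 and durations >= 1")
  }
  for (r in unique(d$run)) {
    dr <- d[d$run == r, , drop = FALSE]
    dr <- dr[order(dr$onset), , drop = FALSE]
    ends <- dr$onset + dr$duration - 1L
    if (nrow(dr) > 1L && any(dr$onset[-1L] <= ends[-nrow(dr)])) {
      stop_value("overlapping intervals in run ", r)
    }
  }
  class(d) <- c("design_table", "data.frame")
  d
}

#' Read a tab-delimited design table
#'
#' Expects a header line `run onset duration condition`.
#' @param path path to the file.
#' @return a `design_table`.
#' @export
read_design_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c("integer", "integer", "integer",
                                        "character"))
  need <- c("run", "onset", "duration", "condition")
  if (!identical(names(d), need)) {
    stop_value("design table must have header: ", paste(need, collapse = " "))
  }
  design_table(d$run, d$onset, d$duration, d$condition)
}

#' Write a design table as tab-delimited text
#' @param design a `design_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_design_table <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Expand a design table to per-observation labels
#'
#' Maps each observation of `ts` to its condition label, optionally shifting
#' labels forward by `lag` observations to account for hemodynamic delay
#' (labels falling past the end of a run are dropped). Unlabeled observations
#' get `""`.
#'
#' @param ts a `voxel_ts`.
#' @param design a `design_table`.
#' @param lag forward shift in observations (default 0).
#' @return character vector of length `ncol(ts$values)`.
#' @export
design_labels <- function(ts, design, lag = 0L) {
  L <- ncol(ts$values)
  labels <- character(L)
  run_start <- match(unique(ts$run_id), ts$run_id)   # first obs of each run
  names(run_start) <- unique(ts$run_id)
  run_len <- table(ts$run_id)
  for (i in seq_len(nrow(design))) {
    r <- as.character(design$run[i])
    if (!r %in% names(run_start)) next
    first <- run_start[[r]]
    len <- run_len[[r]]
    rel <- design$onset[i] + lag
    span <- rel:(rel + design$duration[i] - 1L)
    span <- span[span >= 1L & span <= len]
    if (any(design$onset[i] + design$duration[i] - 1L > len)) {
      stop_value("design interval exceeds run ", r, " length (", len, ")")
    }
    labels[first - 1L + span] <- design$condition[i]
  }
  labels
}

# ---- detrending ------------------------------------------------------------

#' Remove per-run linear drift
#'
#' Within each run independently, subtracts from every voxel's series its
#' least-squares line (intercept + slope * t). The per-run, per-voxel mean of
#' the residual is zero, and the operation is idempotent. Only a first-order
#' drift model is offered, matching the preprocessing convention for scanner
#' drift.
#'
#' @param ts a `voxel_ts`.
#' @return a detrended `voxel_ts` with the same annotations.
#' @export
detrend_linear <- function(ts) {
  stopifnot(inherits(ts, "voxel_ts"))
  vals <- ts$values
  for (r in unique(ts$run_id)) {
    cols <- which(ts$run_id == r)
    if (length(cols) < 3L) {
      stop_value("run ", r, " has fewer than 3 observations; cannot detrend")
    }
    tt <- seq_along(cols)
    X <- cbind(1, tt)
    # closed-form least squares per voxel, vectorized over voxels
    coef <- t(solve(crossprod(X), crossprod(X, t(vals[, cols, drop = FALSE]))))
    vals[, cols] <- vals[, cols, drop = FALSE] - coef %*% t(X)
  }
  ts$values <- vals
  ts
}
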