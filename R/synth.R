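# Synthetic multi-run fMRI generator with planted ground truth.
#
# Emulates a category-localizer + event-related-task session: block-design
# localizer runs (12 blocks alternating 30 s task / 30 s control at TR 2 s,
# i.e. 15 observations per block) and event-related task runs (4 categories
# x 50 stimuli, 4 s trials, a 4 s blank after every five trials, spread over
# three runs of 70/70/60 trials). Planted voxel classes: strongly activated
# sources, weakly activated voxels, near-exact duplicates of the strong
# sources (redundant information), and pure Gaussian noise. The response
# model is a lag-shifted boxcar/impulse — no hemodynamic convolution — so
# expected statistics stay analytic.

#' Specification of a synthetic dataset
#'
#' Defaults encode the emulated acquisition: TR 2 s, 12-block localizer runs
#' (6 task + 6 control, 15 observations = 30 s per block), 4 categories x 50
#' stimuli in three task runs of 70/70/60 trials. Effect sizes are response
#' amplitudes in noise-SD units; `effect_size_strong = 1.5` and
#' `effect_size_weak = 0.5` are engineering choices (true per-voxel fMRI
#' effect sizes are unknowable), chosen so strong voxels are comfortably
#' detectable by a t contrast within one run and weak voxels are not.
#'
#' @param n_voxels total voxels (default 192 on an 8x8x4 grid).
#' @param grid_shape 3-D grid the voxels occupy (capacity must cover
#'   `n_voxels`; rows fill the grid in x-fastest order).
#' @param categories stimulus category labels (default the four object
#'   categories animal/building/car/face).
#' @param n_stimuli_per_category event-related trials per category (50).
#' @param blocks_per_run localizer blocks per run (12, alternating task and
#'   control starting with task).
#' @param block_observations observations per block (15, i.e. 30 s at TR 2 s).
#' @param task_run_trials stimulus trials per task run (70, 70, 60).
#' @param strong_fraction,weak_fraction fraction of voxels planted as strong
#'   / weak responders (rounded to an equal per-category count).
#' @param redundancy_copies near-exact copies planted per strong source
#'   voxel (default 2).
#' @param effect_size_strong,effect_size_weak response amplitudes in units
#'   of `noise_sd`.
#' @param duplicate_jitter SD of the independent noise added to a duplicate,
#'   in units of `noise_sd` (default 0.05, giving pairwise r > 0.99).
#' @param hemodynamic_lag_observations forward shift of the response
#'   relative to stimulus timing (default 1 observation = 2 s).
#' @param noise_sd SD of the voxel noise (default 1; signal units are
#'   arbitrary).
#' @param trend_slope_range range of the per-voxel, per-run linear drift
#'   slope, in signal units per observation (default `c(-0.01, 0.01)`).
#' @param ar_phi AR(1) coefficient of the temporal noise (default 0 =
#'   white).
#' @param tr_seconds repetition time (2 s).
#' @param seed layout seed: fixes which voxels are planted where, shared by
#'   every run generated from this spec.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_voxels = 192L,
                           grid_shape = c(8L, 8L, 4L),
                           categories = c("animal", "building", "car", "face"),
                           n_stimuli_per_category = 50L,
                           blocks_per_run = 12L,
                           block_observations = 15L,
                           task_run_trials = c(70L, 70L, 60L),
                           strong_fraction = 0.04,
                           weak_fraction = 0.12,
                           redundancy_copies = 2L,
                           effect_size_strong = 1.5,
                           effect_size_weak = 0.5,
                           duplicate_jitter = 0.05,
                           hemodynamic_lag_observations = 1L,
                           noise_sd = 1,
                           trend_slope_range = c(-0.01, 0.01),
                           ar_phi = 0,
                           tr_seconds = 2,
                           seed = 1L) {
  spec <- list(n_voxels = as.integer(n_voxels),
               grid_shape = as.integer(grid_shape),
               categories = as.character(categories),
               n_stimuli_per_category = as.integer(n_stimuli_per_category),
               blocks_per_run = as.integer(blocks_per_run),
               block_observations = as.integer(block_observations),
               task_run_trials = as.integer(task_run_trials),
               strong_fraction = strong_fraction,
               weak_fraction = weak_fraction,
               redundancy_copies = as.integer(redundancy_copies),
               effect_size_strong = effect_size_strong,
               effect_size_weak = effect_size_weak,
               duplicate_jitter = duplicate_jitter,
               hemodynamic_lag_observations = as.integer(hemodynamic_lag_observations),
               noise_sd = noise_sd,
               trend_slope_range = trend_slope_range,
               ar_phi = ar_phi,
               tr_seconds = tr_seconds,
               seed = as.integer(seed))
  class(spec) <- "synthetic_spec"
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  nc <- length(spec$categories)
  n_strong <- nc * max(1L, as.integer(round(spec$strong_fraction *
                                              spec$n_voxels / nc)))
  n_weak <- nc * max(1L, as.integer(round(spec$weak_fraction *
                                            spec$n_voxels / nc)))
  planted <- n_strong * (1L + spec$redundancy_copies) + n_weak
  if (planted > spec$n_voxels) {
    stop_value("infeasible fractions: ", planted,
               " planted voxels exceed n_voxels = ", spec$n_voxels)
  }
  if (prod(spec$grid_shape) < spec$n_voxels) {
    stop_value("grid capacity ", prod(spec$grid_shape),
               " below n_voxels = ", spec$n_voxels)
  }
  if (spec$blocks_per_run %% 2L != 0L) {
    stop_value("blocks_per_run must be even (alternating task/control)")
  }
  if (sum(spec$task_run_trials) !=
      length(spec$categories) * spec$n_stimuli_per_category) {
    stop_value("task_run_trials must sum to n_categories * n_stimuli_per_category")
  }
  invisible(spec)
}

#' Ground-truth voxel layout of a synthetic spec
#'
#' Deterministic given `spec$seed`: every run generated from the same spec
#' shares this layout. Strong sources are placed in per-category contiguous
#' clumps (consecutive x-fastest rows), weak voxels and duplicates as
#' scattered singletons, so searchlight's preference for focal effects and
#' blindness to isolated voxels are both reproducible.
#'
#' @param spec a `synthetic_spec`.
#' @return a list of class `synth_truth`: `strong`, `weak` (row indices),
#'   `duplicate_groups` (list of index vectors, source first),
#'   `category_of_voxel` (per-voxel category or `NA`), `noise` (indices).
#' @export
synth_ground_truth <- function(spec) {
  n <- spec$n_voxels
  nc <- length(spec$categories)
  per_cat_strong <- max(1L, as.integer(round(spec$strong_fraction * n / nc)))
  per_cat_weak <- max(1L, as.integer(round(spec$weak_fraction * n / nc)))
  n_strong <- nc * per_cat_strong
  with_seed(spec$seed + 104729L, {
    cat_of <- rep(NA_character_, n)
    # strong clumps: one contiguous run of rows per category, spaced evenly
    clump_starts <- as.integer(round(seq(1L, n - per_cat_strong,
                                         length.out = nc)))
    strong <- integer(0)
    for (ci in seq_len(nc)) {
      rows <- clump_starts[ci] + seq_len(per_cat_strong) - 1L
      while (any(rows %in% strong)) rows <- rows + per_cat_strong
      strong <- c(strong, rows)
      cat_of[rows] <- spec$categories[ci]
    }
    remaining <- setdiff(seq_len(n), strong)
    # duplicates and weak voxels: scattered singletons
    dup_groups <- list()
    if (spec$redundancy_copies > 0L) {
      dup_rows <- sample(remaining, n_strong * spec$redundancy_copies)
      remaining <- setdiff(remaining, dup_rows)
      for (si in seq_along(strong)) {
        copies <- dup_rows[(si - 1L) * spec$redundancy_copies +
                             seq_len(spec$redundancy_copies)]
        dup_groups[[si]] <- c(strong[si], copies)
        cat_of[copies] <- cat_of[strong[si]]
      }
    } else {
      dup_groups <- as.list(strong)
    }
    weak <- sort(sample(remaining, nc * per_cat_weak))
    cat_of[weak] <- rep(spec$categories, length.out = length(weak))
    noise <- setdiff(seq_len(n), c(strong, unlist(dup_groups), weak))
  })
  structure(list(strong = sort(strong), weak = weak,
                 duplicate_groups = dup_groups,
                 category_of_voxel = cat_of, noise = noise),
            class = "synth_truth")
}

# per-voxel amplitude vector for a stimulus category
category_amplitudes <- function(spec, truth, category) {
  amp <- numeric(spec$n_voxels)
  match_cat <- !is.na(truth$category_of_voxel) &
    truth$category_of_voxel == category
  strongish <- sort(unique(unlist(truth$duplicate_groups)))
  amp[match_cat & seq_len(spec$n_voxels) %in% strongish] <-
    spec$effect_size_strong * spec$noise_sd
  amp[match_cat & seq_len(spec$n_voxels) %in% truth$weak] <-
    spec$effect_size_weak * spec$noise_sd
  amp
}

# noise matrix n x L, optionally AR(1), plus per-voxel linear trend
synth_noise <- function(spec, L) {
  n <- spec$n_voxels
  eps <- matrix(stats::rnorm(n * L, sd = spec$noise_sd), n, L)
  if (spec$ar_phi != 0) {
    scale <- sqrt(1 - spec$ar_phi^2)   # keep marginal SD at noise_sd
    eps[, 1L] <- eps[, 1L]
    for (t in 2L:L) {
      eps[, t] <- spec$ar_phi * eps[, t - 1L] + scale * eps[, t]
    }
  }
  slope <- stats::runif(n, spec$trend_slope_range[1L],
                        spec$trend_slope_range[2L])
  eps + outer(slope, 0:(L - 1L))
}

# overwrite duplicate rows with source + jitter
apply_duplicates <- function(values, spec, truth) {
  if (spec$redundancy_copies == 0L) return(values)
  for (grp in truth$duplicate_groups) {
    src <- grp[1L]
    for (cp in grp[-1L]) {
      values[cp, ] <- values[src, ] +
        stats::rnorm(ncol(values), sd = spec$duplicate_jitter * spec$noise_sd)
    }
  }
  values
}

synth_voxel_index <- function(spec) {
  arrayInd(seq_len(spec$n_voxels), .dim = spec$grid_shape) - 1L
}

#' Generate one block-design localizer run
#'
#' One category's localizer run: `blocks_per_run` blocks alternating task and
#' control (task first), category-matching planted voxels responding with a
#' boxcar shifted by the hemodynamic lag, duplicates tracking their source
#' up to jitter, everything else pure noise plus drift.
#'
#' @param spec a `synthetic_spec`.
#' @param category the run's stimulus category.
#' @param seed noise seed for this run (layout comes from `spec$seed`).
#' @param run_id run label recorded in the outputs (default 1).
#' @return list with `ts` (a `voxel_ts`), `design` (a `design_table` of the
#'   12 blocks), and `truth` (the `synth_truth`).
#' @export
generate_localizer_run <- function(spec, category, seed, run_id = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!category %in% spec$categories) {
    stop_value("unknown category '", category, "'")
  }
  truth <- synth_ground_truth(spec)
  L <- spec$blocks_per_run * spec$block_observations
  block_cond <- rep(c(category, "control"), spec$blocks_per_run / 2L)
  onsets <- (seq_len(spec$blocks_per_run) - 1L) * spec$block_observations + 1L
  design <- design_table(run = rep(run_id, spec$blocks_per_run),
                         onset = onsets,
                         duration = rep(spec$block_observations,
                                        spec$blocks_per_run),
                         condition = block_cond)
  box <- numeric(L)
  for (b in which(block_cond == category)) {
    box[onsets[b] + seq_len(spec$block_observations) - 1L] <- 1
  }
  lag <- spec$hemodynamic_lag_observations
  resp <- if (lag > 0L) c(numeric(lag), box[seq_len(L - lag)]) else box
  amp <- category_amplitudes(spec, truth, category)
  values <- with_seed(seed, {
    v <- synth_noise(spec, L) + outer(amp, resp)
    apply_duplicates(v, spec, truth)
  })
  ts <- voxel_time_series(values, voxel_index = synth_voxel_index(spec),
                          grid_shape = spec$grid_shape,
                          run_id = rep(run_id, L),
                          condition = design_labels_from_run(design, run_id, L),
                          tr_seconds = spec$tr_seconds)
  list(ts = ts, design = design, truth = truth)
}

design_labels_from_run <- function(design, run_id, L) {
  lab <- character(L)
  d <- design[design$run == run_id, , drop = FALSE]
  for (i in seq_len(nrow(d))) {
    lab[d$onset[i] + seq_len(d$duration[i]) - 1L] <- d$condition[i]
  }
  lab
}

#' Generate a full localizer session (one run per category)
#'
#' @param spec a `synthetic_spec`.
#' @param seed session seed; per-run noise seeds are derived from it.
#' @return list with the concatenated `ts`, the combined `design`
#'   (run ids 1..n_categories in category order), and `truth`.
#' @export
generate_localizer_session <- function(spec, seed) {
  seeds <- derive_seeds(seed, length(spec$categories))
  runs <- lapply(seq_along(spec$categories), function(ci) {
    generate_localizer_run(spec, spec$categories[ci], seeds[ci], run_id = ci)
  })
  ts <- do.call(concat_runs, lapply(runs, `[[`, "ts"))
  design <- do.call(rbind, lapply(runs, `[[`, "design"))
  class(design) <- c("design_table", "data.frame")
  list(ts = ts, design = design, truth = runs[[1L]]$truth)
}

concat_runs <- function(...) {
  parts <- list(...)
  voxel_time_series(do.call(cbind, lapply(parts, function(p) p$values)),
                    parts[[1L]]$voxel_index, parts[[1L]]$grid_shape,
                    unlist(lapply(parts, function(p) p$run_id)),
                    unlist(lapply(parts, function(p) p$condition)),
                    parts[[1L]]$tr_seconds)
}

#' Generate the event-related task runs
#'
#' All stimuli (`n_categories * n_stimuli_per_category`, default 200) in
#' randomized order, split across runs per `spec$task_run_trials`
#' (default 70/70/60). Each stimulus trial spans 2 observations (4 s at TR
#' 2 s); a 2-observation blank trial follows every five stimulus trials.
#' Category-matching planted voxels respond over the lag-shifted trial
#' window; duplicates track their sources.
#'
#' @param spec a `synthetic_spec`.
#' @param seed seed for trial order and noise.
#' @return list with `ts`, `design` (one row per stimulus or blank trial),
#'   and `truth`.
#' @export
generate_task_runs <- function(spec, seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  truth <- synth_ground_truth(spec)
  trial_len <- 2L
  n_runs <- length(spec$task_run_trials)
  stim_cats <- rep(spec$categories, each = spec$n_stimuli_per_category)
  seeds <- derive_seeds(seed, n_runs + 1L)
  order_all <- with_seed(seeds[n_runs + 1L],
                         sample.int(length(stim_cats)))
  stim_cats <- stim_cats[order_all]
  run_values <- vector("list", n_runs)
  run_ids <- vector("list", n_runs)
  design_rows <- list()
  offset <- 0L
  amps <- lapply(spec$categories, function(cc)
    category_amplitudes(spec, truth, cc))
  names(amps) <- spec$categories
  lag <- spec$hemodynamic_lag_observations
  for (r in seq_len(n_runs)) {
    n_trials <- spec$task_run_trials[r]
    cats_r <- stim_cats[offset + seq_len(n_trials)]
    offset <- offset + n_trials
    n_blank <- n_trials %/% 5L
    # trailing rest so the lag-shifted window of the last trial stays in-run
    L <- (n_trials + n_blank) * trial_len + lag + trial_len
    # trial schedule: blank after every 5 stimulus trials
    onset <- 1L
    stim_i <- 0L
    rows <- list()
    signal <- matrix(0, spec$n_voxels, L)
    while (stim_i < n_trials) {
      stim_i <- stim_i + 1L
      cc <- cats_r[stim_i]
      rows[[length(rows) + 1L]] <-
        data.frame(run = r, onset = onset, duration = trial_len,
                   condition = cc, stringsAsFactors = FALSE)
      win <- onset + lag + seq_len(trial_len) - 1L
      win <- win[win <= L]
      signal[, win] <- signal[, win] + amps[[cc]]
      onset <- onset + trial_len
      if (stim_i %% 5L == 0L && stim_i < n_trials) {
        rows[[length(rows) + 1L]] <-
          data.frame(run = r, onset = onset, duration = trial_len,
                     condition = "blank", stringsAsFactors = FALSE)
        onset <- onset + trial_len
      }
    }
    # trailing rest, recorded as a final blank so the design tiles the run
    rows[[length(rows) + 1L]] <-
      data.frame(run = r, onset = onset, duration = L - onset + 1L,
                 condition = "blank", stringsAsFactors = FALSE)
    run_values[[r]] <- with_seed(seeds[r], {
      v <- synth_noise(spec, L) + signal
      apply_duplicates(v, spec, truth)
    })
    run_ids[[r]] <- rep(r, L)
    design_rows <- c(design_rows, rows)
  }
  design <- do.call(rbind, design_rows)
  design <- design_table(design$run, design$onset, design$duration,
                         design$condition)
  values <- do.call(cbind, run_values)
  run_id <- unlist(run_ids)
  lab <- character(ncol(values))
  start <- c(0L, cumsum(vapply(run_values, ncol, 1L)))
  for (r in seq_len(n_runs)) {
    lab[start[r] + seq_len(ncol(run_values[[r]]))] <-
      design_labels_from_run(design, r, ncol(run_values[[r]]))
  }
  ts <- voxel_time_series(values, synth_voxel_index(spec), spec$grid_shape,
                          run_id, lab, spec$tr_seconds)
  list(ts = ts, design = design, truth = truth)
}

#' Generate one synthetic subject (localizer session + task runs)
#'
#' @param spec a `synthetic_spec`.
#' @param seed subject seed; the voxel layout follows `spec$seed`, the
#'   noise and trial order follow `seed`.
#' @return list with `localizer` (ts/design), `task` (ts/design), `truth`,
#'   and the `spec` used.
#' @export
generate_subject <- function(spec, seed) {
  seeds <- derive_seeds(seed, 2L)
  loc <- generate_localizer_session(spec, seeds[1L])
  task <- generate_task_runs(spec, seeds[2L])
  list(localizer = loc[c("ts", "design")], task = task[c("ts", "design")],
       truth = loc$truth, spec = spec)
}

#' Generate a cohort of synthetic subjects
#'
#' Stands in for a multi-subject experiment: per-subject seeds (layout and
#' noise) are derived deterministically from `master_seed`, and each
#' subject's effect sizes are jittered by up to `effect_jitter` (default
#' +/-20%) to create the between-subject variability a paired
#' across-subject comparison needs.
#'
#' @param spec the cohort-level `synthetic_spec`.
#' @param n_subjects number of subjects.
#' @param master_seed cohort seed.
#' @param effect_jitter relative uniform jitter of the effect sizes.
#' @return list of subjects as returned by [generate_subject()].
#' @export
generate_subject_cohort <- function(spec, n_subjects, master_seed,
                                    effect_jitter = 0.2) {
  stopifnot(n_subjects >= 1L)
  seeds <- derive_seeds(master_seed, 2L * n_subjects)
  lapply(seq_len(n_subjects), function(s) {
    jit <- with_seed(seeds[s], stats::runif(2, 1 - effect_jitter,
                                            1 + effect_jitter))
    spec_s <- spec
    spec_s$effect_size_strong <- spec$effect_size_strong * jit[1L]
    spec_s$effect_size_weak <- spec$effect_size_weak * jit[2L]
    spec_s$seed <- seeds[s]          # independent voxel layout per subject
    generate_subject(spec_s, seeds[n_subjects + s])
  })
}
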