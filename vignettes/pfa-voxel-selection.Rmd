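---
title: "Principal feature analysis for fMRI voxel selection: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Principal feature analysis for fMRI voxel selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfaselect)
```

## The model

MVPA decoding treats each trial's multivoxel activity pattern as a vector
and classifies it. Voxel selection decides which coordinates of that vector
the classifier sees. `pfaselect` implements three selectors sharing one
contract (a `voxel_ts` in, a `selected_features` out) and one evaluation
harness.

**Principal feature analysis.** Let `Y` be the `n × L` voxel/observation
matrix of a localizer run, and `Σ` its voxel-by-voxel dependency matrix —
correlation by default, covariance optionally. Eigendecomposing
`Σ = A Λ Aᵀ` and truncating to the first `q` eigenvectors gives `A_q`,
whose *rows* `a_i ∈ R^q` are the projections of each voxel onto the
retained component space. Two voxels whose time courses are strongly
dependent have nearly collinear rows, so clustering the rows under cosine
distance groups redundant voxels. PFA keeps, per cluster, the single
original voxel whose row is closest to the cluster center: a subset that
covers the dependency structure without duplicating it, and whose members
remain physically interpretable voxels (unlike PCA scores). Finally each
representative is scored by `|e_1[i]|`, its loading magnitude on the
leading eigenvector; representatives of pure-noise clusters load weakly on
the dominant shared signal and are truncated away.

Assumptions worth stating: the dependency matrix is estimated from one
run's observations, so `L` must be comfortably larger than the number of
strong shared components (block designs help); linear dependency is what
correlation sees — nonlinearly coupled voxels will not share clusters; and
anti-correlated voxels are *not* treated as redundant, because cosine
distance places a row and its negation at maximal distance (see "Numerical
choices").

**Comparators.** The univariate selector scores each voxel by the pooled
two-sample |t| between task and control observations; the searchlight
selector re-scores each voxel by the mean |t| over the 33-voxel sphere of
radius 2 centered on it, truncated at the mask boundary.

**Evaluation.** Trial patterns (selected voxels averaged over a
post-onset window) feed a stratified k-fold cross-validated linear SVM;
similarity matrices are pattern-pair correlations after subtracting each
voxel's mean response across all patterns; selectors are compared across
subjects with the exact Wilcoxon signed-rank test.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `mode` | correlation | — | voxel variances sit on an arbitrary scanner scale; covariance offered for fidelity to the original formulation |
| `variance_fraction` | 0.90 | fraction of total eigenvalue mass | the source criterion for `q` is unstated anywhere authoritative; 0.90 mirrors the retained-variability convention of the PFA literature |
| `oversample_factor` | 1.2 | clusters per requested voxel | `k = min(n, ceil(1.2 · N))` gives the leading-eigenvector filter some noise representatives to discard; 1.0 reproduces unfiltered PFA |
| `n_restarts` | 10 | — | Lloyd iterations from one random start are seed-fragile; best-of-10 by within-cluster objective stabilizes the output (single-restart mode available) |
| `max_iter` | 300 | iterations | guard; assignment fixed point is the convergence test |
| `lag_observations` | 1 | observations (2 s at TR 2 s) | crude hemodynamic delay for the t contrast; a stand-in for a full GLM, which is out of scope |
| `radius` | 2 | voxels | the canonical 33-voxel searchlight sphere |
| `n_folds` | 5 | — | the evaluation protocol's fold count |
| SVM cost `C` | 1 | — | fixed; linear kernel, one-vs-rest; no hyperparameter search, keeping the comparison deterministic |
| `window_offsets` | 1–2 | observations post-onset | ≈2–4 s after trial onset at TR 2 s; how trial patterns were formed upstream is unknowable, so this is a documented choice |

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` encodes a category-localizer + event-related session:
12-block localizer runs alternating 30 s task / 30 s control (15
observations per block at TR 2 s), one run per category; 4 categories × 50
stimuli in three task runs of 70/70/60 trials of 4 s each, with a 4 s blank
after every five trials and a short trailing rest per run. Planted voxel
classes: *strong* sources (d = 1.5 noise-SD response amplitude, placed in
per-category contiguous clumps), *weak* voxels (d = 0.5, scattered
singletons), *duplicates* (source + 5%-SD jitter, pairwise r > 0.99), and
pure noise. Defaults: 192 voxels on an 8×8×4 grid, 2 strong sources and 6
weak voxels per category, 2 duplicates per source, per-voxel linear drift
with slope in ±0.01 signal-units/observation. Effect sizes are engineering
choices — true per-voxel fMRI effect sizes are unknowable — picked so a
single localizer run detects strong voxels reliably and weak voxels
unreliably, which is the regime where selector differences matter.
Per-subject cohorts jitter effect sizes ±20% to create the between-subject
variability a paired test needs.

The response model is a lag-shifted boxcar/impulse, *not* a convolved
hemodynamic response; noise is Gaussian, optionally AR(1), with no
physiological structure, no motion, no spatial autocorrelation beyond the
planted duplicates, and no anatomical geometry. A green end-to-end test
therefore establishes that the algorithms behave as specified under their
own assumptions — redundancy is collapsed, weak signal is retained, the
direction of the selector comparison reproduces — not that the same
margins would appear on any particular scanner dataset.

## Numerical choices

- **Eigenvector sign convention.** Eigensolvers return columns up to sign;
  each column is flipped so its largest-magnitude entry is nonnegative
  (first such entry on ties), making projection rows reproducible. Note
  this fixes *basis* ambiguity only: negating a voxel's data still negates
  its row, and under cosine distance that voxel legitimately moves to an
  antipodal cluster. Treating anti-correlated voxels as redundant would
  require absolute-cosine clustering, which the underlying formulation
  does not use.
- **`choose_q`** clamps tiny negative eigenvalues to zero and takes the
  smallest `q` reaching the variance target; at a target of exactly 1 it
  returns the last strictly positive eigenvalue's index.
- **k-means degeneracies.** Ties in assignment go to the lowest cluster
  id; an emptied cluster is repaired by moving in the row farthest from
  its own center (never emptying another); a zero-norm member mean keeps
  the previous center; zero-norm rows are given distance 1 to every
  center. All selection ties break toward the lowest voxel index, so every
  pipeline output is deterministic given its seed.
- **Restart selection** compares objectives with a 1e-12 slack so exact
  ties keep the earliest restart.
- **Detrending** fits intercept + slope per run per voxel by closed-form
  least squares; it is idempotent to 1e-9 and refuses runs shorter than 3
  observations. A sampled sine over whole periods still has nonzero
  least-squares slope — detrending is *not* a high-pass filter and is
  documented (and tested) as exactly line removal.
- **Wilcoxon signed-rank** drops zero differences, uses average ranks for
  ties, and computes the exact tie-aware null by convolution over doubled
  ranks (identical to 2^n sign enumeration) up to n = 25, switching to the
  tie-corrected, continuity-corrected normal approximation above. The
  in-package implementation exists because the stock test refuses exact
  p-values under ties.
- **Linear SVM** is solved by dual coordinate descent on the hinge loss
  with a fixed sweep order (deterministic); features are standardized with
  training-fold statistics only, so no test-set leakage.

## Design choices where the design was genuinely open

- *"5-fold leave-one-out cross-validation"* is self-contradictory as a
  protocol name; it is implemented as stratified 5-fold CV — one portion
  held out per fold — with folds stratified by category over stimuli (not
  runs).
- The per-category union protocol caps overflow (if a `total_budget` is
  set) by each voxel's maximum cross-category score; the upstream
  description implies overlap between category subsets but states no cap
  rule.
- PFA is unsupervised, so its per-category form runs on each category's
  localizer run; the t/searchlight selectors use that category's
  task-vs-control contrast on the same session.
- The noise filter's "remove features with small scores" has no stated
  threshold; this package oversamples clusters (`oversample_factor`) and
  truncates the ranked representatives to the requested budget, which
  reduces to the unfiltered method at factor 1.0.
- NIfTI-1 I/O and the linear SVM are implemented in-package because the
  target environment ships no R-side implementation of either; both are
  deliberately minimal (single-file NIfTI-1, five dtypes, both byte
  orders; hinge-loss linear SVM with fixed C).

## Known limitations

- PFA's usefulness degrades when the dependency structure is pure noise:
  with `q` close to `n` the rows approach orthonormality and every
  clustering is arbitrary. The leading-eigenvector filter then carries all
  the weight, and at very small signal fractions selection approaches the
  univariate ranking of `|e_1|`.
- The spherical searchlight is scored on a lattice; anisotropic voxel
  sizes are not corrected for (radius is in voxel units, not mm).
- The exact Wilcoxon path is quadratic in the rank sum; above n = 25 the
  normal approximation is used regardless of ties.
- `read_nifti` supports single-file NIfTI-1 only — no `.hdr/.img` pairs,
  NIfTI-2, or datatype codes beyond the five listed in its documentation.
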