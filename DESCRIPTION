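Package: pfaselect
Title: Principal Feature Analysis Voxel Selection for Multivoxel Pattern Analysis
Version: 0.1.0
Authors@R:
    person("pfaselect", "developers", email = "pfaselect@example.org",
           role = c("aut", "cre"))
Description: Feature (voxel) selection for multivoxel pattern analysis of
    functional MRI. Implements principal feature analysis: eigendecomposition
    of the voxel dependency (covariance or correlation) matrix, cosine k-means
    clustering of the eigenvector row projections, per-cluster representative
    selection, and a leading-eigenvector noise filter. Ships the standard
    comparator selectors (univariate t-statistic ranking and spherical
    searchlight average-absolute-t scoring), a per-category selection and
    union protocol, and a decoding evaluation harness (stratified
    cross-validated linear support vector machine, similarity-matrix analysis
    with within/between-category contrast, exact Wilcoxon signed-rank
    comparison). Includes lightweight NIfTI-1 volume input/output and a
    synthetic block-design/event-related fMRI generator with planted
    ground-truth informative, redundant and noise voxels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
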