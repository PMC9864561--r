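Package: mvpafusion
Title: Spatiotemporal Multivariate Decoding and MEG-fMRI Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for spatiotemporal multivariate pattern analysis of
    neuroimaging data: time-resolved pairwise decoding of MEG sensor
    patterns with supertrial averaging and multivariate noise
    normalization, ROI and searchlight decoding of fMRI beta patterns,
    cross-decoding between stimulus families, temporal generalization,
    representational similarity analysis with MEG-fMRI fusion, and the
    accompanying nonparametric statistics (sign-permutation tests,
    cluster-size correction with across-test maxima, FDR, bootstrap
    peak-latency confidence intervals, TOST equivalence). Includes a
    first-level fMRI GLM with per-voxel selection from a library of
    hemodynamic response functions, outlier-volume screening, noise
    component extraction, velocity-threshold microsaccade detection for
    gaze-based trial quality control, and synthetic-data generators with
    known ground truth so every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
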