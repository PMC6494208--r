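Package: numdecode
Title: Decoding, Searchlight and Connectivity Analysis of Numerical
    Magnitude fMRI Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for group studies of numerical magnitude processing with
    functional MRI: first-level general linear models yielding per-run
    condition t-patterns, subject-level region-of-interest definition with
    hierarchical gated FDR group testing, pairwise multivoxel decoding of
    numerosities with within-format averaging, whole-volume searchlight
    decoding with permutation-based family-wise error control, subject
    classification with leave-one-pair-out cross-validation and Monte
    Carlo permutation tests, seed-based functional connectivity with
    Fisher z statistics, and summary-statistics group tests for behavioral
    and diffusion tract metrics. A synthetic cohort generator reproduces
    the block-design structure of a two-group numerosity comparison
    experiment so that every stage can be exercised and calibrated without
    scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    signal,
    jsonlite,
    RNifti
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
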