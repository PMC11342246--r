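Package: recide
Title: Ensemble Cell-Type Deconvolution with Subject-Specific Single-Cell References
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates cell-type proportions in bulk expression profiles by
    running a single-reference deconvolution (dampened weighted least squares
    or non-negative least squares) against every subject of a multi-subject
    single-cell reference, then integrating the per-subject estimates through
    principal-component reduction, Gaussian-mixture clustering, and averaging
    over the largest cluster. Includes subject-wise marker-gene selection by
    cosine scoring, a second-fold-change specificity filter, condition-number
    driven signature-matrix construction, greedy bulk-similarity marker
    refinement, a synthetic multi-subject reference and pseudo-bulk generator
    with known ground truth, and an evaluation suite (RMSE, Pearson
    correlation, abundance-class regression slopes, leave-one-out
    benchmarking, and a perivascular-like-cell prognostic score).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    mclust,
    pracma,
    jsonlite,
    methods,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
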