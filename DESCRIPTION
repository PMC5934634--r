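Package: onedhic
Title: One-Dimensional Explicit Bias and Copy-Number Normalization of Hi-C Contact Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Explicit normalization of binned Hi-C contact matrices through their
    one-dimensional contact profile. Per-bin totals are modeled with a negative
    binomial generalized additive model on genomic covariates (G+C content, read
    mappability, restriction-site counts); the rescaled fitted means yield a
    correction vector applied to every matrix entry. An optional copy-number
    correction infers per-bin copy number from the corrected profile with an
    eight-state hidden Markov model with Student-t emissions and divides each
    entry by the square root of the inferred copy numbers. Also provides the
    matrix-balancing baselines (vanilla, ICE, Knight-Ruiz), observed-over-expected
    transformation, four matrix-reproducibility metrics (banded Spearman,
    observed/expected Pearson, stratum-adjusted correlation, spectral Laplacian
    score) with a ROC evaluation harness, and a simulator generating Hi-C matrices
    with distance decay, smooth per-bin biases and injected copy-number aberrations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    mgcv,
    rtracklayer,
    GenomicRanges,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
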