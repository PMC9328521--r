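Package: tcam
Title: Tensor Component Analysis for Longitudinal Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dimensionality reduction for longitudinal omics studies via
    tensor component analysis (tcam). Subject-by-feature-by-timepoint data
    are factorized with the tubal singular value decomposition (tsvdm)
    under the star-M tensor-tensor product, yielding per-subject trajectory
    scores, per-feature loadings, explained-variance fractions, and an
    out-of-sample projection for unseen subjects. Includes compositional
    and baseline normalization front-ends (robust centered log-ratio,
    deviation from baseline, log-fold baseline), assembly of tidy
    long-format tables into fully sampled tensors with naive imputation,
    loadings-based feature interpretation utilities, and a synthetic
    longitudinal data generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
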