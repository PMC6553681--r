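Package: radtex
Title: Texture Radiomics of Masked Brain MRI Regions
Version: 0.1.0
Authors@R:
    person("radtex", "developers", email = "radtex@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for texture radiomics of masked 3D brain MRI
    regions, aimed at two-class tissue classification problems such as
    detecting the presence or subtype of ischaemic stroke. Computes 114
    named texture descriptors per masked volume (grey-level co-occurrence
    and run-length matrices, rotation-invariant local binary patterns, and
    Haar wavelet statistical and co-occurrence features) via per-slice 2D
    extraction with median aggregation, screens features with Mann-Whitney
    U tests under Holm-Bonferroni family-wise error control, and evaluates
    linear support vector machine and random forest classifiers with
    repeated stratified cross-validation and fold-internal filter feature
    selection (Mann-Whitney p-value or maximal information coefficient
    rankings). Includes a synthetic phantom cohort generator so the whole
    pipeline is testable without patient data, minimal NIfTI-1 input and
    output, and a command-line interface chaining the stages.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
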