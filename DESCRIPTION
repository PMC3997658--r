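Package: rsfcnet
Title: Seed-Network Resting-State Functional Connectivity Analysis with
    Permutation Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis of resting-state functional MRI connectivity within
    a-priori networks of spherical volumes of interest placed at stereotaxic
    (MNI) peak coordinates. Provides eigenvariate time-series extraction,
    nuisance regression and temporal band-pass filtering of BOLD data,
    Fisher-z edge connectivity, balanced-design site deconfounding,
    Monte-Carlo permutation group inference with false-discovery-rate
    control, effect sizes, within-group coupling classification, patient
    subgroup and symptom-correlation analyses, and head-motion quality
    control (DVARS, framewise displacement, RMS). Includes a synthetic
    two-site, two-group BOLD cohort generator with known ground-truth edge
    connectivity so that every pipeline stage is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    RNifti,
    signal,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
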