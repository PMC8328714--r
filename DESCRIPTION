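Package: strokeseg
Title: Stroke Lesion Segmentation with a Multi-Loss U-Net, Dense-CRF
    Refinement and Small-Vessel-Disease Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end desk-scale pipeline for ischemic stroke lesion
    segmentation on multimodal brain MRI: a synthetic multimodal phantom
    generator with known ground truth, an encoder-decoder convolutional
    network with a crop layer and a dual-weighted auxiliary loss, fully
    connected conditional random field refinement by exact mean-field
    inference, connected-component postprocessing driven by time-to-peak
    perfusion and relative component volume, a surface-distance evaluation
    suite (Hausdorff, average symmetric surface distance, Dice, precision,
    recall), and deterministic cerebral small vessel disease burden scoring
    with the Montreal Cognitive Assessment cut-off.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    oro.nifti,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
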