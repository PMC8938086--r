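Package: sonodx
Title: Multimodal Ultrasound Diagnostics and Tissue-Marker Scoring for
    Small Liver Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for the quantitative side of multimodal ultrasound
    diagnosis of small hepatocellular carcinoma: adaptive median
    filtering and simple augmentation of B-mode images, volumetric
    overlap error (VOE) consensus across annotators, confusion-matrix
    and average-precision segmentation evaluation, rule-based
    benign/malignant calls per ultrasound modality with AND-rule
    fusion, diagnostic performance statistics (sensitivity,
    specificity, accuracy, Cohen's kappa with interpretation bands),
    and semiquantitative immunohistochemistry positivity scoring for
    EZH2 and p57. A synthetic-data module simulates speckle- and
    impulse-corrupted phantoms with ground-truth masks, multi-annotator
    mask sets, a four-arm patient cohort with per-grade imaging-feature
    frequencies, and marker expression tables, so the whole pipeline
    runs end to end without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
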