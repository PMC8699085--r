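Package: msidistill
Title: Adversarial Bias Ablation for Microsatellite-Instability Prediction
    from Tissue Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and remove batch effects in deep-learning models
    that predict microsatellite instability (MSI) from haematoxylin-eosin
    tissue-microarray (TMA) images. Provides a synthetic TMA tile generator
    with controllable label-correlated stain shifts, glass tints and
    patient-level signatures; spot tiling at multiple magnifications with
    Macenko stain normalization and tissue-type filtering; a squared
    distance-correlation audit of learned representations against protected
    variables with subgroup (backward-selection) analysis; a feature
    extractor with an MSI head and per-bias adversarial heads trained by a
    three-step min-max schedule with y-conditioned correlation losses; and
    patient-level majority-vote aggregation with prevalence-adjusted
    screening metrics and exact/logit confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    png,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
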