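Package: maft
Title: Multimodal Adaptive-Fusion Transformer Models for Depression Severity Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates PHQ-8 depression severity from multimodal frame-level
    feature streams (acoustic and facial descriptors in the AVEC style). Each
    feature type is encoded by a transformer encoder trained with a joint
    concordance-correlation-coefficient (CCC) regression loss and an auxiliary
    five-class severity classification loss; per-feature predictions are
    combined by CCC-weighted adaptive late fusion, optionally restricted to the
    top-M features ranked by validation CCC. Includes segment-based frame
    subsampling for long sequences, sliding-window functional (mean/sd)
    features, a synthetic multimodal cohort generator with a planted severity
    signal for end-to-end testing, and broom-style tidiers plus ggplot2
    autoplot methods for fitted models and fusion results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
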