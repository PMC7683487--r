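Package: digitsim
Title: Glyph-Similarity Predictors and Mixed-Model Analysis of Speeded Digit Comparison
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling speeded relative-quantity ("is the digit
    greater or less than five?") experiments in which the same quantities are
    shown in Arabic or Mandarin numeral formats. Provides curated line-segment
    encodings of both numeral systems and the segment-overlap physical
    similarity score P = O/D computed from them, the Welford log-ratio
    numerical-distance predictor, a trial-level synthetic-experiment generator
    with participant-varying slopes, deadline censoring and response errors,
    and an analysis pipeline (outlier trimming, log transform, mixed-effects
    regression with per-participant slopes, condition comparison, and
    inter-participant slope correlations) together with parameter-recovery
    simulation harnesses.
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
    lme4,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    patchwork
Config/testthat/edition: 3
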