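Package: picturesort
Title: Scoring and Psychometric Evaluation of Picture-Sort Dietary
    Assessment Instruments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores picture-sort food-frequency instruments into healthy
    eating indices (a six-component modified Alternative Healthy Eating
    Index, a healthy foods score, fruit and vegetable subscores, and the
    ratio of healthy-to-total daily servings), scores 4-point Likert
    psychosocial scales (tendency to choose and self-efficacy for fruits
    and vegetables), and runs a psychometric evaluation pipeline:
    internal consistency with a single-item removal rule, convergent
    validity against reference measures with a retention filter, and
    Bland-Altman test-retest reliability.  Includes a synthetic
    two-timepoint cohort generator with known ground truth so every
    pipeline stage can be exercised and calibrated without access to
    restricted study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
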