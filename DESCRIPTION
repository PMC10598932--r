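Package: chemogram
Title: Chemogram Scoring for Ex Vivo Drug Sensitivity Screens on
    Patient-Derived Organoids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns raw 96-well ATP-luminescence readings from drug tests on
    patient-derived organoids (PDOs) into per-drug sensitivity scores and hit
    calls. Triplicate wells are normalized to solvent controls, conditions
    with unstable replicates are excluded by a standard-error rule, and each
    PDO x drug dose-response profile receives a two-part final score: a
    cohort-relative AUC score plus an absolute sensitivity score. Includes
    cohort-level analytics (response heterogeneity, drug-drug Pearson
    correlation with hierarchical clustering, hit counts, Welch group
    comparisons), diagnostic concordance of PDO hit calls against matched
    patients' clinical responses, a synthetic screen generator with ground
    truth for validation, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
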