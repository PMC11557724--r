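Package: chemotox
Title: Chemotherapy Toxicity Risk Stratification, Fairness Auditing and
    Multi-Site Shift Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and auditing machine-learning risk
    stratification models for chemotherapy-induced renal and hepatic
    dysfunction. Includes a multi-site synthetic cohort generator with
    configurable data shift, toxicity rates and blood-test missingness;
    CTCAE-style grade ladders and grade-change-toward-toxicity labelling;
    gradient-boosted regression models under fixed-early and rolling
    prediction framings with sensitivity-optimised 1.4x decision
    thresholds; F-beta model evaluation with subgroup performance tables;
    Generalised Entropy Index fairness measures (individual and
    between-group); and cross-site feature-distribution shift reporting
    with fine-versus-broad subgroup-aggregation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
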