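Package: fallrisk
Title: Multifactorial Fall-Risk Modelling from Robotic Balance Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating multifactorial fall-risk
    models in older adults from robotic balance-platform and trunk-IMU
    recordings. Extracts standard posturographic indicators (95% prediction
    ellipse sway area, sway path, oscillation ranges, trunk variability,
    limits-of-stability reaches), segments platform-perturbation epochs and
    five-times-sit-to-stand phases, assembles clinical and robotic features
    into per-subject cohort tables, fits L1-penalized logistic risk models
    under nested stratified cross-validation with a full discrimination
    metric suite (ROC AUC with DeLong confidence intervals, average
    precision, Youden-cutoff operating characteristics, Matthews
    correlation), and compares competing models by continuous net
    reclassification improvement and integrated discrimination improvement.
    A synthetic-data module generates protocol-compliant session recordings
    and feature-level cohorts so every pipeline stage can be exercised and
    validated without access to patient data.
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
    glmnet,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
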