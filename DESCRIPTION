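Package: anomalyqc
Title: Centroid-Distance Anomaly Detection for Clinical Registry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-quality screening for clinical registries captured in
    entity-attribute-value (EAV) electronic data capture systems. Flattens
    per-patient form instances into prefix and semi-flattened wide tables,
    preprocesses them (variable dropping, median/mode imputation, temporal and
    categorical recoding, min-max normalisation), and flags anomalous records
    by their distance to the global centroid under an ensemble of seven
    distance metrics with percentile/IQR thresholds. Includes a seeded
    synthetic-registry generator, a ground-truth anomaly-injection simulator
    (6-sigma shifts for normal variables, rare-interval draws otherwise), ROC
    threshold calibration with the C1 criterion, exhaustive union-rule
    ensemble search with the C2 criterion, and automatic data-manager query
    generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
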