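Package: microskill
Title: Vessel-Deformation and Instrument-Kinematics Assessment of
    Microsurgical Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies microvascular anastomosis performance from
    per-frame vessel segmentation areas and instrument-tip trajectories.
    Computes vessel-area variability (CV-VA), relative area change
    (delta-VA), tissue-deformation-error counts against a cohort
    threshold, path distance, and the normalized jerk index, stratified
    by surgical phase; aggregates surgeon-level representative values;
    screens parameters against a nine-category criteria-based rating
    scale by Spearman rank correlation; and discriminates good from poor
    performance with Fisher linear discriminant models evaluated by ROC
    curves with bootstrap confidence intervals. Includes a synthetic
    cohort generator with controllable latent skill so every stage is
    testable without surgical video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    png,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    MASS,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
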