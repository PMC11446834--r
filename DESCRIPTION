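Package: eflkit
Title: Expiratory Flow Limitation Assessment from Exercise Flow-Volume Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing expiratory flow limitation (EFL) during
    incremental exercise from pneumotachograph airflow recordings: maximal
    expiratory flow-volume (MEFV) envelope construction from graded forced
    vital capacity maneuvers, linear drift correction of the volume signal,
    breath segmentation and composite averaging of tidal flow-volume loops,
    inspiratory capacity and operating lung volumes, overlap-based EFL
    detection, ventilatory capacity (VE,CAP), and slope-ratio curvature of
    the MEFV descending limb. Includes between-day repeatability statistics
    (Cohen's kappa, intraclass correlation, within-subject coefficient of
    variation, paired t, Fisher's exact) with conventional classification
    bands, and a ground-truth-labelled synthetic two-visit study generator
    for validating the full pipeline.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
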