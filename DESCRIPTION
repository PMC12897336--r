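Package: qolcea
Title: Cost-Utility Analysis of Quality-of-Life-Prediction-Guided Psychosocial Support
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic cost-utility model comparing strategies for
    allocating individual psychosocial support to women treated for early
    breast cancer: clinician prediction of one-year quality of life (QoL),
    clinician prediction aided by a machine-learning QoL predictor, the
    predictor alone, and no prediction with no support. Implements the
    four-strategy decision tree with expected per-patient costs,
    quality-adjusted life years and net monetary benefit under payer and
    societal perspectives; prevalence calibration from published anchors;
    incremental analysis with strict and extended dominance and the
    cost-effectiveness frontier; probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves; and a synthetic patient-cohort
    generator with estimation routines so the full pipeline is testable
    without access to the underlying trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
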