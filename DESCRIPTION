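Package: alkcea
Title: Cost-Effectiveness of ALK Testing and First-Line Crizotinib in
    Advanced NSCLC
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Decision-tree plus three-state Markov cohort model evaluating
    ALK-rearrangement testing (NGS panel or multiplex PCR) followed by
    first-line crizotinib against standard pemetrexed-cisplatin
    chemotherapy in advanced non-small-cell lung cancer, from the Chinese
    healthcare system perspective.  Includes Weibull parametric survival
    handling (evaluation, per-cycle transition probabilities, log-log
    least-squares fitting of digitized Kaplan-Meier points), discounted
    cost/QALY/life-year accrual with a configurable crizotinib patient
    assistance program, incremental cost-effectiveness statistics, one-way
    (tornado) deterministic sensitivity analysis, Monte-Carlo probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves, a
    synthetic-data generator for testing, and a calibration utility for
    the modelling conventions the source tables leave open.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
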