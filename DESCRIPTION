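Package: peerload
Title: Modelling the Demand, Supply and Imbalance of Journal Peer Review
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative modelling of the annual demand for and supply of
    journal peer review. Provides closed-form estimates of total submissions,
    reviews and reviewers from an empirical manuscript-resubmission
    distribution and a reviewer-effort distribution; an author census over
    bibliographic records (MEDLINE-style XML or a simple line format) under
    four reviewer-eligibility scenarios; Monte Carlo simulation of
    per-reviewer annual review hours against a research work-time budget,
    with top-share and work-time imbalance statistics; deterministic
    sensitivity sweeps over the model parameters; and synthetic-data
    generators with known ground truth for every model input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
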