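Package: shockscreen
Title: Disproportionality Signal Detection for Shock Adverse Events in
    Spontaneous Report Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pharmacovigilance screening of
    shock-related adverse events in FAERS-style spontaneous report data:
    quarterly ASCII ingestion, case deduplication and deletion handling,
    healthcare-professional filtering, shock preferred-term extraction,
    four-method disproportionality analysis (reporting odds ratio,
    proportional reporting ratio, Bayesian confidence propagation neural
    network information component, and empirical Bayes geometric mean)
    with combined signal tiers, omega shrinkage screening of
    co-administered drug pairs, descriptive cohort summaries, and
    evaluation of method performance against planted ground truth in a
    bundled spontaneous-report simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
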