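Package: mmsurv
Title: Single-Cell Lineage Survival and Drug-Interaction Analysis for
    Mother-Machine Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how antibiotic combinations act on single
    bacterial lineages tracked in mother-machine microfluidic devices.
    Includes a calibrated stochastic generator of per-cell measurement
    tables (exponential elongation, sizer division, drug-dependent death,
    SOS-reporter dynamics, post-death photobleaching, channel-loss
    censoring), per-generation elongation-rate fitting, lineage fate and
    SOS-class classification, Kaplan-Meier survival estimation with
    right-censoring and log-rank comparisons, Bliss-independence expected
    survival with a one-sided ANOVA contrast test, and suppression
    quantification, chained by a reproducible end-to-end pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    survival,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
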