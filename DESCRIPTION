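Package: faersig
Title: Pharmacovigilance Signal Mining for FAERS-Style Spontaneous Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for disproportionality analysis of spontaneous
    adverse-event reporting data in the dialect of the FDA Adverse Event
    Reporting System (FAERS). Reads the quarterly '$'-delimited ASCII
    tables (DEMO, DRUG, REAC, THER, OUTC), de-duplicates cases, restricts
    to primary-suspect mentions of a user-supplied brand-name dictionary,
    and computes four signal-detection statistics with their conventional
    thresholds: the reporting odds ratio (ROR), proportional reporting
    ratio (PRR), the Bayesian confidence propagation neural network
    information component (IC025), and a simplified empirical-Bayes
    geometric mean (EBGM05). Adds Weibull time-to-onset modelling with
    early/random/wear-out hazard classification, cohort characteristic
    summaries, and a fully deterministic synthetic-FAERS generator with a
    ground-truth manifest for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    fitdistrplus,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
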