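Package: activeEGFR
Title: Quantification of Active EGFR by Fluorogenic-Probe Flow Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying conformationally active EGFR in dissociated
    tumour specimens with a turn-on fluorogenic kinase-inhibitor probe read out
    by multicolor flow cytometry. Implements the competitive-binding occupancy
    and turn-on brightness model, a seeded synthetic single-cell event
    simulator with matched control/stained/blocked tubes, the six-step gating
    strategy with DMSO background correction and a gefitinib-competition
    specificity check, diagnostic-performance statistics (tie-corrected ROC
    AUC, Youden midpoint cut-offs, exact Clopper-Pearson intervals,
    Mann-Whitney tests), a decision-analytic cost model for probe-first versus
    sequencing-only mutation triage, and packaged surgical and biopsy cohort
    tables with loaders and consistency validators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
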