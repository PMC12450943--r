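Package: faersignal
Title: Disproportionality Signal Detection and Time-to-Onset Analysis for
    FAERS Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pharmacovigilance pipeline for FDA Adverse Event Reporting
    System (FAERS) quarterly data: reads the dollar-delimited ASCII tables,
    removes duplicate report versions by the FDA-recommended rule, maps
    MedDRA preferred terms to system organ classes, builds drug-event 2x2
    contingency tables and computes four disproportionality statistics
    (ROR, PRR with the MHRA composite criteria, a BCPNN-style information
    component, and an MGPS-style empirical Bayes geometric mean) with
    positivity flags, models time-to-onset with a maximum-likelihood
    Weibull fit and hazard-type classification, screens drug pairs for
    interaction signals with the Omega shrinkage measure, and runs
    stratified and indication-restricted sensitivity analyses. A synthetic
    FAERS-shaped cohort generator with a ground-truth manifest makes every
    stage testable without downloading the real database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    fitdistrplus,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
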