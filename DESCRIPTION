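Package: rorsignal
Title: Reporting Odds Ratio Signal Detection and Side-Effect Profiling
    for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Disproportionality analysis for FAERS-style spontaneous
    adverse-event report databases. Reads the dollar-delimited quarterly
    extract dialect (DEMO/DRUG/REAC), deduplicates and joins report-level
    tables, and screens drugs for reporting odds ratio (ROR) signals using
    Haldane-corrected 2x2 contingency tables, two-sided Fisher exact tests
    and Wald confidence intervals. Includes demographic (age/gender) and
    ATC drug-class association analysis, characterization of side-effect
    spectra by Ward hierarchical clustering and correlation-matrix
    principal component analysis of drug-by-term lnROR profiles, and a
    configurable synthetic spontaneous-report generator with a ground-truth
    ledger for end-to-end validation. The bundled vocabulary covers the
    taste and smell disorders standardized MedDRA query and an ATC L01
    antineoplastic class map.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
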