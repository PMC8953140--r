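Package: jaundiceclaims
Title: Maternal Disease Factors for Neonatal Jaundice from Insurance Claims
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable case-control pipeline for identifying maternal disease
    factors associated with neonatal jaundice from longitudinal insurance
    claims tables. Builds pregnancy-delivery episodes from diagnosis codes
    under explicit temporal rules, extracts antenatal and pre-conception
    exposure windows, and performs exact 2x2 inference (conditional-MLE odds
    ratio with exact confidence intervals), repeated 1:10 propensity-score
    matching with a stability criterion, and stratified conditional logistic
    regression. Ships a synthetic claims generator emulating a national
    sample-cohort layout with planted episodes and known odds ratios, so every
    stage is testable without access to the non-public source data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse
Config/testthat/edition: 3
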