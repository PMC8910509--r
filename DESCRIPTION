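Package: esvland
Title: Ecosystem Service Valuation, Land-Use Accounting and Driver Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for equivalence-factor ecosystem service valuation (ESV) on
    categorical land-use rasters: reclassification and zonal area accounting,
    land-use transition matrices and single land-use dynamic degrees, the ESV
    coefficient matrix and all ESV aggregates, an area-weighted human impact
    index, and driver attribution with gradient-boosted regression trees and
    exact interventional Shapley values (with a brute-force subset-enumeration
    oracle). Ships the published coefficient and valuation tables for the
    Dongting Lake eco-economic zone as machine-readable fixtures, and a
    synthetic landscape generator with Markov land-cover dynamics and planted
    driver effects for end-to-end testing with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    tibble,
    rlang,
    jsonlite,
    yaml,
    xgboost,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
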