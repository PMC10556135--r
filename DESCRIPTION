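Package: raschdif
Title: Semi-Automated Rasch Scale Construction with Differential Item
    Functioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for semi-automated construction of clinimetric scales
    from ordinal questionnaire responses in the presence of differential
    item functioning (DIF).  Fits the generalized partial credit model
    extended with group-specific uniform DIF offsets (GPCM-DIF) by
    penalized joint maximum likelihood, using two-level coordinate
    descent with a lasso (L1) penalty that shrinks irrelevant DIF
    parameters to exactly zero.  Item selection maximizes the
    in-plus-out-of-questionnaire log likelihood with DIF (IPOQ-LL-DIF)
    via alternating backward elimination and forward selection.
    Includes standard Rasch diagnostics (Infit/Outfit mean squares,
    residual correlations, person separation reliability,
    Cronbach-Mesbah curves, random-instrument baselines, hypergeometric
    overlap probabilities), a response simulator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
LinkingTo:
    Rcpp
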