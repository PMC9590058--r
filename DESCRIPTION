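Package: peddose
Title: Weight-Based Pediatric Dose Prediction for Therapeutic Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts first-in-pediatric doses of therapeutic proteins
    (monoclonal antibodies, polyclonal antibodies, and non-antibody
    proteins) from the adult regimen with the Salisbury weight rule, and
    evaluates predictions against per-kilogram extrapolated,
    clearance-ratio based, or investigator-selected observed doses using
    percent and fold prediction errors with the conventional 0.5-1.5-fold
    and 0.7-1.3-fold accuracy bands. Includes a synthetic cohort
    generator with allometric clearance scaling, a CSV cohort schema,
    stratified summary tables, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    tibble,
    withr,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
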