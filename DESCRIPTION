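Package: awlr
Title: Attribute-Weighted Logistic Regression for Adverse Drug Event Severity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts severe versus non-severe adverse drug events with a
    logistic regression whose maximum-likelihood coefficients are adjusted by
    chi-square derived attribute weights under a sign-preserving rule.
    Includes supervised entropy/minimum-description-length discretization of
    continuous attributes, information-gain and Kullback-Leibler baseline
    weighting schemes, balanced-sampling repeated cross-validation with
    accuracy/precision/recall/F-score reporting, data preparation utilities
    for pharmacovigilance records (therapy duration, dose unit conversion,
    severity labelling), and a reproducible generator of FAERS-like synthetic
    adverse-event datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
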