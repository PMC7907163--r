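Package: fcfingerprint
Title: Connectivity Fingerprinting of Reading Skill with Dual-Task Neural Network Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for task-based functional-connectivity fingerprinting of
    reading skill. Builds labelled connectivity patterns (Pearson correlation
    and binned cross-mutual information over split-half ROI time series) from
    region-of-interest BOLD data, trains dual-output multilayer perceptron
    classifiers that simultaneously decode reading-skill group and stimulus
    lexicality, iteratively prunes features by summed path-weight attribution
    across independent model families, assembles a composite model of reliably
    predictive connections with class-specific network extraction, and tests
    cross-task transfer of the group fingerprint. Includes a synthetic-cohort
    generator with planted group- and condition-dependent coupling so the full
    pipeline is testable without access to raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
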