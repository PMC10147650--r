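Package: gipace
Title: Gastrointestinal Pacemaker Activity Features and Adverse-Effect
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts 24 electrical features from multi-electrode
    gastrointestinal slow-wave recordings made before and after acute drug
    treatment, merges the normalized feature changes with a SIDER-style
    adverse-effect label table, and runs a classification protocol
    (t-test feature refinement, five classifier families plus an ensemble,
    seven randomized half/half splits, and a Gaussian random-dataset
    control) to produce per-drug adverse-effect probability reports and a
    drug-effect similarity network. Includes a seeded synthetic-study
    generator (grid slow-wave simulator, drug-effect libraries with
    receptor-class structure, planted feature-to-adverse-effect rules) so
    the whole pipeline is testable without access to laboratory
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    MASS,
    e1071,
    rpart,
    class,
    igraph,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
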