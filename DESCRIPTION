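Package: paleoSDM
Title: Hindcast Species Distribution Models for Fossil Validation and
    Taxonomic Assignment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for validating hindcast species distribution models
    against dated fossil occurrences and for reducing fossil taxonomic
    uncertainty by comparing hindcast climatic suitability at a fossil's
    location and age against each candidate species' minimum present-day
    occurrence suitability.  Provides presence-background maximum-entropy,
    logistic-regression and random-forest suitability models with the
    settings commonly used in paleodistribution studies, AUC and
    true-skill-statistic cross-validation, multivariate environmental
    similarity (MESS/MoD) and clamping diagnostics for non-analogue
    climates, and a virtual-species simulator that generates paleoclimate
    stacks, occurrence samples and planted fossils with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
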