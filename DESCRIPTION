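Package: consensusVS
Title: Consensus Ligand- and Structure-Based Virtual Screening for
    Bioinsecticide Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for prioritizing multi-target, low-toxicity
    bioinsecticide candidates by fusing ligand-based and structure-based
    evidence. Trains and validates random-forest activity classifiers on
    molecular-descriptor matrices (stratified partitioning, pooled
    cross-validation, sensitivity/specificity/accuracy/PPV/NPV, Matthews
    correlation coefficient, ROC analysis, and a Euclidean applicability
    domain), normalizes docking energies against a reference inhibitor into
    activity probabilities, combines both channels into a specificity-weighted
    consensus probability with a strict selection threshold, intersects
    selections across target enzymes, and filters candidates on four
    toxicity-risk parameters. Includes seeded synthetic-library generators for
    end-to-end benchmarking and alignment-derived active-site conservation
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ChemmineR,
    jsonlite,
    randomForest,
    stats,
    tibble,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
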