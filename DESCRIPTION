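Package: pssmDBP
Title: DNA-Binding Protein Prediction from PSSM Evolutionary Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies DNA-binding proteins from evolutionary profiles.
    Parses PSI-BLAST ASCII position-specific scoring matrices (PSSMs),
    extracts three complementary descriptor blocks (AADP-PSSM,
    PSSM-COMPOSITION and a reduced-alphabet RPSSM) and fuses them into a
    930-dimensional feature vector per protein. Features are ranked by a
    max-relevance/max-distance (MRMD) criterion, an optimal prefix subset
    is chosen by incremental cross-validated accuracy, and a random forest
    classifies proteins as DNA-binding or not, reporting accuracy,
    sensitivity, specificity, Matthews correlation and ROC/AUC. A
    synthetic PSSM generator with controllable class signal makes the full
    pipeline testable without running PSI-BLAST.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    ranger,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
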