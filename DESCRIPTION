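Package: pfasttr
Title: QSAR Models for Human Transthyretin Disruption by PFAS
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification (linear discriminant analysis) and regression
    (ordinary least squares) quantitative structure-activity relationship
    models for the disruption of human transthyretin (hTTR) by per- and
    polyfluoroalkyl substances (PFAS). Provides native computation of the
    seven modelling descriptors (Geary and centered Broto-Moreau 2D
    autocorrelations, mass-weighted neighborhood-symmetry information
    content, bond-order path counts, and Galvez topological charge
    indices) from SMILES, compound curation and endpoint derivation,
    structure-ranked dataset splitting, step-up variable selection with
    leave-one-out bootstrap overfitting control, descriptor-randomization
    and Y-scrambling validation, leverage- and cosine-similarity-based
    applicability domains with uncertainty quantification, the published
    fixed-coefficient models, and a sequential classify-then-quantify
    screening workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    pROC,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
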