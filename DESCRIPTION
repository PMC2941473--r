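Package: minitox
Title: Desk-Scale Interoperable Predictive Toxicology Framework
Version: 0.1.0
Authors@R: person("minitox", "developers", role = c("aut", "cre"),
    email = "minitox@example.org")
Description: A self-contained, desk-scale re-implementation of an
    interoperable predictive-toxicology (QSAR) framework: a small-molecule
    chemistry core (SMILES subset parsing, canonical forms, path
    fingerprints, Tanimoto similarity, physico-chemical descriptors), a
    compound/feature/dataset store with CSV, SDF V2000 and RDF (Turtle and
    RDF/XML) exchange, an algorithm registry with representative payloads
    (descriptor calculation, chi-squared feature selection,
    similarity-weighted k-nearest-neighbour classification, least-squares
    regression), applicability-domain estimation, an independent validation
    service with reproducible split plans and standard classification and
    regression metrics (confusion matrix, precision/recall/F-beta, ROC/AUC,
    MSE/RMSE/R-squared), an ontology and task hub, report generation, and
    two end-user workflows for predicting the toxicity of a structure and
    for creating and validating a model from a user dataset. A synthetic
    fixture generator plants a toxicophore signal so the whole stack is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    digest,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
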