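Package: kmosar
Title: Activity Modeling, Chemical Space Networks and Field-Based QSAR for
    Kynurenine 3-Monooxygenase Inhibitors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end structure-activity modeling pipeline for small
    molecule enzyme inhibitors, exercised on human kynurenine
    3-monooxygenase (hKMO) inhibitor series. Covers activity-data curation
    (deduplication, ranged-value filtering, pIC50 conversion),
    physicochemical profiling with Pearson correlation structure, an
    interpretable tree-ensemble activity classifier with mutual-information
    and importance-based feature selection, exact tree-Shapley explanations
    and partial dependence, leverage-based applicability domain analysis,
    Tanimoto chemical space networks with modularity communities, and a
    grid-based 3D/4D field-QSAR engine (Lennard-Jones and Coulomb probe
    energies over conformer ensembles) fitted by NIPALS partial least
    squares with full internal and external validation statistics.
    Includes a synthetic-data generator that plants known
    structure-activity effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    rpart,
    randomForest,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
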