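Package: ligaff
Title: Contact-Based Prediction of Protein-Ligand Binding Affinity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores protein-ligand complexes with a linear binding-affinity
    model built from element-typed intermolecular atomic contacts and a
    shifted-Coulomb electrostatic energy term, and retrains that model from
    tabulated affinity data (Ki to free-energy conversion, ordinary least
    squares, AIC stepwise selection, k-fold cross-validation).  A companion
    ligand-based predictor computes Carhart atom-pair fingerprints from SD
    files, Tanimoto similarity kernels, and support vector regression on the
    precomputed kernel.  Includes pose-averaged scoring, ligand ranking,
    Kendall tau-b / Pearson ranking evaluation, positive-predictive-value and
    enrichment-factor curves, ligand RMSD after receptor-backbone
    superposition, and deterministic generators for toy complexes, synthetic
    training tables and toy molecule sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    ChemmineR,
    jsonlite,
    kernlab,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
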