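Package: featGO
Title: Feature-Based Gene Ontology Term Prediction for Protein Sequences
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Homology-free prediction of Gene Ontology (GO) terms for
    protein sequences via per-term binary support vector machines trained
    on groups of biophysical sequence features (amino-acid composition,
    predicted secondary structure, transmembrane helices, intrinsic
    disorder, signal peptides, sequence motifs and related attributes).
    Includes the surrounding machinery needed to train and benchmark such
    predictors offline: an OBO 1.2 ontology parser with "is a" annotation
    propagation and information-content estimation, naive frequency and
    sequence-similarity transfer baselines, protein-centric
    precision/recall/Fmax evaluation with top-l trimming and tie
    resampling, statistics for functional conservation and divergence
    across alternative splice isoforms, and generators for synthetic
    ontologies, proteomes and isoform catalogues with planted
    feature-to-function structure.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.3), methods
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Classification, FunctionPrediction, GO, Software
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'features.R'
    'ontology.R'
    'svm.R'
    'baselines.R'
    'evaluation.R'
    'featGO-package.R'
    'fixtures.R'
    'published.R'
    'splicing.R'
    'utils.R'
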