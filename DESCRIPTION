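Package: SeqTolerance
Title: Flexible-Backbone Prediction of Tolerated Protein Sequence Space
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts the sequence space tolerated by a protein fold or
    interface using a two-stage flexible-backbone protocol: backbone
    ensembles are generated by backrub Monte Carlo, low-energy sequences
    are enriched per backbone with a genetic algorithm over a precomputed
    pairwise interaction graph, and Boltzmann-weighted sequences are merged
    across backbones into a position weight matrix. Includes a pluggable
    residue-pairwise energy contract with a simplified reference potential,
    side-chain packing by simulated annealing, resfile/movemap input
    dialects, profile evaluation metrics (AUC, AAD, bits of information,
    rank statistics) and deterministic synthetic fixtures for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Proteomics, StructuralPrediction, Software
RoxygenNote: 7.3.3
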