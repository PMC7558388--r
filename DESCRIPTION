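Package: PhoreScreen
Title: Ligand-Based Pharmacophore Perception, Matching and Virtual Screening
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A ligand-based pharmacophore engine built around the five-point
    bradykinin B1/B2 receptor antagonist model: rule-based feature perception
    (positive charge, hydrogen-bond donor/acceptor, aromatic, hydrophobic),
    distance-geometry embedding of pharmacophore distance matrices with
    3D-realizability diagnostics, tolerance-based correspondence matching of
    conformer ensembles against distance matrices, seeded stochastic
    distance-geometry conformer generation with force-field refinement, and an
    end-to-end virtual screening pipeline with molecular-weight filtering and
    receptor-selectivity labeling. Ships the consensus (P1-P4) and
    receptor-specific (P5) bradykinin pharmacophores and a fixture library of
    eight approved drugs plus constructed decoys for screen validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    ChemmineOB,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: Cheminformatics, Pharmacogenomics, StructuralPrediction
RoxygenNote: 7.3.3
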