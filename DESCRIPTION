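Package: voroscore
Title: Voronoi Interface Descriptors and Collaborative-Filtering Re-Ranking
    for Protein-Protein Docking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse-grain (one node per residue) Voronoi modelling of
    protein-protein interfaces and a complete docking re-ranking stack built
    on it: rigid-body candidate generation by pseudo-normal pairing, a
    96-attribute Voronoi interface descriptor with explicit missing-value
    semantics, a centered linear scoring function trained by a (mu+lambda)
    evolution strategy maximizing ROC AUC under complex-level
    cross-validation, a precision-weighted collaborative-filtering ensemble
    of binary classifiers, hybrid CF-GA fusion, and CAPRI-style quality
    assessment (fnat, interface RMSD, ligand RMSD, quality classes,
    enrichment and report tables). Includes deterministic synthetic-fixture
    generators so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    e1071,
    rpart,
    tree,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
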