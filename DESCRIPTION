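Package: proteofp
Title: Hashed Residue-Neighborhood Protein Fingerprints for Proteo-Chemometric Potency Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes protein 3D structures as hashed residue-neighborhood
    binary fingerprints, encodes ligands as 2048-bit ECFP6 circular
    fingerprints, curates Ki bioactivity records into a scaled potency score
    (spKi) in [0, 1], and fits a single random-forest model over joined
    ligand and PCA-projected protein features. Supports baseline per-target
    QSAR, unified, blind (leave-target-out) and semi-blind (structurally
    paired leave-target-out) validation regimes with RMSE and ratio of
    variance explained, plus a synthetic-data generator with a planted
    structure-activity signal for end-to-end testing without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
SystemRequirements: Python (>= 3.8) with RDKit, available as `python` on the
    PATH (used only for ligand ECFP6 fingerprints).
Config/testthat/edition: 3
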