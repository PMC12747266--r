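Package: ic50net
Title: Hybrid Graph-Attention and Descriptor Regression of IC50 Potency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative structure-activity (QSAR) regression of log10 IC50
    potency from SMILES. Molecules are encoded two ways in parallel: as
    molecular graphs whose node vocabulary is the element-hybridization tuple
    (Csp3 and Csp2 are distinct node classes), processed by a two-layer
    edge-conditioned graph attention network with mean/max readout; and as a
    544-dimensional descriptor vector (512-bit Morgan fingerprint plus 32
    physicochemical descriptors) processed by a feed-forward branch. The two
    embeddings are fused with a molecular-size feature and regressed to
    log10 IC50 (nM). Includes a ChEMBL-style activity-table cleaning pipeline
    (validation, unit harmonisation, median deduplication, log transform,
    seeded splitting and per-target oversampling), a deterministic synthetic
    molecule and activity generator for end-to-end testing, training with
    smooth-L1 loss and Adam, R2/RMSE/MAE evaluation overall and per target,
    and a command-line interface. Chemistry (parsing, canonicalisation,
    descriptors, fingerprints) is delegated to RDKit through a bundled
    Python helper.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: Python (>= 3.8) with the rdkit package, available as
    'python' on the PATH.
Config/testthat/edition: 3
RoxygenNote: 7.3.3
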