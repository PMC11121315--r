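Package: tmhc
Title: Inter-Helical Residue Contact Prediction from Transmembrane Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts inter-helical residue-residue contacts in alpha-helical
    transmembrane proteins from 3D structures. Geometric structure-derived
    features (relative residue distances, relative residue angle and
    inter-helical tilt angle over a 3x3 sequence-window neighbourhood) are
    extracted per candidate residue pair and fed to a small feed-forward
    neural classifier; a raw-coordinate feature baseline, a binary contact-map
    baseline, per-sequence average-precision/AUC/top-L evaluation with
    sequence-level cross-validation, and a synthetic helix-bundle generator
    with a coordinate-noise model are included.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
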