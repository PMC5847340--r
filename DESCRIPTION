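Package: PiPiContacts
Title: Planar Pi-Pi Contact Detection, Survey Statistics and Phase-Separation
    Propensity Scoring
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects face-to-face planar pi-pi contacts between sp2 groups in
    protein crystal structures using a distance- and orientation-based
    geometric criterion, computes survey statistics of contact frequencies
    (per-residue involvement, resolution dependence, solvation and secondary
    structure profiles, interface breakdowns, sp3 controls), predicts expected
    pi-contact frequencies per sp2 group from sequence context, and converts
    those predictions into a phase-separation propensity score (PScore)
    through a trainable weighted window-average model. Includes seeded
    synthetic generators for geometry fixtures, contact-annotation corpora
    and composition-controlled sequence sets, plus empirical ROC/AUC and
    sequence-complexity evaluation utilities and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: StructuralBioinformatics, Proteomics, Classification
RoxygenNote: 7.3.3
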