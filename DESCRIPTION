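Package: memmatch
Title: Hydrophobic Mismatch Analysis of Transmembrane Helix Dimers
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of transmembrane (TM) helix dimers in
    planar lipid bilayers: dimer tilt and crossing angles defined from
    center-of-mass segments spanning the GVxxGVxxT dimerization motif,
    least-squares (Kabsch) superposition with RMSD/RMSF series,
    Kabsch-Sander alpha-helicity assignment, gridded membrane thickness
    and perturbation maps with a far-field bulk reference, the
    1.5 Angstrom-per-residue hydrophobic-length rule and mismatch
    classification, and dimerization-assay statistics (normalization,
    relative fluorescence, merged-homodimer fold change, Student's t,
    Benjamini-Hochberg q-values). Includes a synthetic ground-truth
    generator (ideal helical dimers in pseudo-bilayers, assay plate
    tables) so every estimator is testable without molecular dynamics,
    plus fixed-column PDB and GRO readers/writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
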