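Package: bitterqsar
Title: QSAR and Interaction Profiling of Polyphenols at the Bitter Taste
    Receptor T2R46
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Structure-activity analysis pipeline for polyphenol ligands of
    the human bitter taste receptor T2R46. Provides a heavy-atom molecule
    model with SMILES/SDF/PDB input, topological descriptors (centrally the
    Wiener path number and molecular weight) plus a configurable descriptor
    pool, a water-probe molecular-interaction-field surface-area descriptor,
    genetic-algorithm descriptor selection with ordinary-least-squares QSAR
    fitting, train/test and leave-one-out cross-validation, the frozen
    published two-descriptor binding-energy model, geometric typing of
    receptor-ligand contacts (hydrogen bonds, salt bridges, CH-pi and pi-pi
    stacking) with per-residue population maps, and synthetic-data
    generators that emulate the study's inputs end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    bio3d,
    jsonlite,
    yaml,
    ChemmineR,
    ChemmineOB,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
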