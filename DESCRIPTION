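Package: glycofc
Title: Fc Glycan Dynamics, Receptor Hinge Geometry, SPR Kinetics and
    Glycan Mass Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for the quantitative analyses used in
    structural studies of engineered multimeric IgG1 Fc (hexa-Fc) and its
    lectin and Fc-receptor interactions: interdomain (D1-D2) hinge-angle
    measurement on PDB structures and multi-model trajectories, 3 Angstrom
    contact counting and two-state classification of N-glycan
    configurations along molecular-dynamics trajectories, a geometric test
    of glycan accessibility to a lectin carbohydrate-recognition domain,
    simulation and global fitting of 1:1 Langmuir surface plasmon
    resonance sensorgrams, and permethylated sodiated N-glycan mass
    computation with MALDI-TOF peak-list annotation. Ships seeded
    synthetic-data generators so every analysis is testable end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
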