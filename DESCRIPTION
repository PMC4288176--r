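Package: quadgeom
Title: Geometric Analysis of G-Quadruplex Structures and Conformational
    Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Structural analysis toolkit for DNA G-quadruplexes and their
    conformational ensembles. Detects G-quartets from Hoogsteen
    hydrogen-bond cycles, assembles the stacked quartet core and channel
    axis, assigns channel cations and classifies fold topology (tracts,
    propeller/lateral/diagonal loops, strand sense, snapback guanines).
    Computes the seven standard nucleic-acid backbone torsions, classifies
    extra-helical bases as up/down/out/stacked relative to the quartet
    core, measures inter-strand phosphorus cleft widths, and profiles
    per-residue flexibility (normalized crystallographic B factors,
    ensemble RMSF, theoretical B factors). Conformational ensembles can be
    clustered with PAM-style k-medoids on RMSD dissimilarities, with
    silhouette-based model selection and same-trajectory transition
    graphs. A seeded synthetic-structure generator builds idealized
    quadruplexes from internal coordinates (known torsions, planted loop
    orientations, channel ions), Gaussian-perturbed ensembles with
    prescribed per-residue fluctuations, and multi-trajectory frame sets
    with planted cluster centers and transition schedules, so every
    analysis stage is testable with known ground truth.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
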