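Package: poresym
Title: Pore Hydration, Sidechain Dynamics, and Proton Flux Analysis for
    Designed Pentameric Channels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trajectory and liposomal-assay analyses linking glutamine
    sidechain dynamics, pore hydration, and water-mediated hydrogen-bond
    network topology to proton conduction in designed pentameric helical
    bundles. Computes sidechain orientation vectors and z-offsets relative
    to the glutamine C-alpha plane, three-state up/neutral/down
    classification and 5x5 pairwise state-agreement matrices, chi1/chi2
    dihedral extraction with density-based rotamer clustering and periodic
    kernel-density background contours, pore water counting within a
    pentagonal anchor region with residence times, z-binned water density
    profiles and hydrophobic lengths from second-derivative inflection
    points, wet/dry frame classification, water-bridged hydrogen-bond
    network graphs with occupancy filtering, and ratiometric HPTS
    fluorescence conversion to pH and buffered total proton concentration
    with initial-rate fitting and one-way ANOVA/Tukey comparisons. A
    synthetic-data generator produces ground-truth-labelled trajectories
    and plate-reader traces so every stage is testable without molecular
    dynamics or laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    jsonlite
Config/testthat/edition: 3
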