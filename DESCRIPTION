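Package: pepdmd
Title: Event-Driven Square-Well Dynamics and Cross-Linking MS Tools for
    Amyloid Peptide Self-Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discontinuous (event-driven) molecular dynamics for a
    coarse-grained square-well peptide model in the PRIME20 style (three
    backbone beads and one sidechain bead per residue, directional
    square-well backbone hydrogen bonds, Andersen thermostat), aimed at
    beta-sheet self-assembly of short amyloidogenic peptides such as
    Abeta16-22 (Ac-KLVFFAE-NH2).  Includes trajectory observables
    (hydrogen-bond maps, beta-sheet residue content, strand-pair
    orientation and registry classification, oligomer clustering, nearest
    interpeptide sidechain contacts), ideal beta-sheet lattice fixtures
    with ground-truth labels, and an in-silico interpretation layer for
    photo-induced cross-linking mass spectrometry: exact mass arithmetic
    for diazirine-modified peptides and cross-linked dimers, b/y fragment
    enumeration with cross-link bookkeeping, cross-link site localization,
    and traveling-wave ion-mobility collision-cross-section calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
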