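Package: fuzzyscape
Title: Dynamics of Disordered Proteins Diffusing on Folded Ligand Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how an intrinsically disordered protein
    moves on the surface of a folded binding partner, integrating
    single-molecule FRET photon analysis with coarse-grained simulation.
    Includes sequence charge analytics (net charge, sequence charge
    decoration, mean-field polyampholyte salt response), conversions between
    polymer distance distributions and FRET observables, a one-bead-per-residue
    hydropathy-scale (HPS) heteropolymer simulator with Debye-Hueckel
    electrostatics and tunable native contacts, trajectory observables
    (scaling-exponent maps, contact statistics, surface coverage), photon-level
    burst analysis (efficiency histograms, recoloring, nanosecond FCS,
    recurrence analysis of single particles), and a diffusive-landscape layer
    (Smoluchowski dynamics in a potential of mean force, Zwanzig roughness,
    Arrhenius and viscosity-corrected temperature models). Seeded synthetic
    generators provide ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    bio3d,
    seqinr,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
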