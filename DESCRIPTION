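Package: amyloidIMS
Title: Ion-Mobility Mass-Spectrometry Analysis of Amyloid-Beta Oligomerization Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for native ion-mobility mass spectrometry of
    amyloid-beta (Abeta42) oligomers. Provides isotope-resolved assignment of
    oligomer order and charge from driftscope (m/z x drift time) frames,
    traveling-wave collision cross-section (CCS) calibration, isotropic and
    linear growth-model fitting with regime-crossover detection, collision-
    induced unfolding/dissociation (CIU/CID) transition analysis with
    energy-gap regimes and ligand-bound comparisons, time-resolved LILBID
    monomer-over-oligomer kinetics, and projection-approximation theoretical
    CCS from cropped fibril structures. A seeded synthetic-data generator
    emulates the instrument so every stage is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    bio3d,
    deSolve,
    minpack.lm,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
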