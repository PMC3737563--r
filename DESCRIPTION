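Package: redcat
Title: Operator-Site Mapping by Reusable-DNA-Capture Surface Plasmon Resonance
Version: 0.1.0
Authors@R: person("ReDCaT", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A toolkit for mapping transcription-factor operator sites with
    surface plasmon resonance (SPR) on a reusable DNA-capture chip. Designs
    the oligonucleotide panels that drive the experiments (overlapping tiling
    fragments, serial truncation series for footprinting, single-base
    substitution panels, linker-bearing capture constructs), processes
    sensorgram cycles (double referencing, report-point extraction,
    theoretical-Rmax normalization, dissociation and salt-wash retention),
    fits steady-state 1:1 Langmuir affinities, calls binding-site footprints
    at 2-bp resolution, derives pseudopalindromic IUPAC consensus motifs and
    scans genomes for them. Includes a seeded synthetic-experiment generator
    so every analysis stage is testable without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
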