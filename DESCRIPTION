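Package: farmarker
Title: Marker-Gene Detection of Far-Red (Chlorophyll f) Cyanobacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for discovering and exploiting the apcE2 marker of
    far-red light photoacclimation (FaRLiP) in cyanobacteria. Finds
    discriminative conserved windows ("far-red islands") that separate
    far-red apcE2 from white-light apcE1 in a two-class multiple
    alignment, designs tagged degenerate PCR primers against them,
    predicts amplicons in silico, screens contigs and short reads for the
    diagnostic VIPEDV-like motif by six-frame translation, and places
    recovered fragments among reference sequences by p-distance and
    neighbor-joining. Includes a seeded synthetic two-class gene-family
    generator so the whole pipeline is testable without any database
    access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
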