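Package: holoassay
Title: Effective-Medium Analysis of Holographic Molecular Binding Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for label-free bead-based binding assays read
    out by holographic particle characterization. Inverts nanometer-scale
    bead diameter shifts into molecular-coating properties (grafting
    density, brush thickness, coating volume fraction) using Maxwell
    Garnett effective-medium theory combined with Gaussian polymer-brush
    scaling; estimates optical specific volumes from refractometer dilution
    series; and implements the multi-population assay workflow with
    population gating in the diameter-index plane, Kolmogorov-Smirnov
    replicate consistency checks, pooling, and internal reference-bead
    drift correction. Includes a forward synthetic-data generator for
    per-particle characterization tables so every stage can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
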