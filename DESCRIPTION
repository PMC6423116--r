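Package: doughnet
Title: Gluten Network Microstructure and Rheology of Wheat Dough
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Structure-function analysis of wheat dough. Quantifies the
    gluten protein network in binary or grayscale confocal micrographs by
    skeleton-based morphometry (branching rate, end-point rate, average
    protein length, protein width) and gliding-box lacunarity; fits a
    power-law model to oscillatory frequency sweeps and four/five parameter
    Burgers models to creep-recovery curves; links microstructure to
    rheology with NIPALS partial least squares (leave-one-out
    cross-validation, Root Mean PRESS factor selection, VIP scores) and
    with frozen published prediction equations; and classifies samples
    into six gluten network types by lacunarity range and attribute
    direction patterns relative to a standard dough. A synthetic-data
    module generates archetype micrographs, rheometer curves and linked
    attribute tables so every stage can be exercised without measured
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    igraph,
    jsonlite,
    EBImage,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mixOmics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
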