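Package: tethermorph
Title: Single-Molecule Morphometry of Coiled-Coil Tethers in AFM Topographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of atomic force microscopy (AFM) height
    images of long dimeric coiled-coil proteins such as Golgi tethers.
    Provides a seeded synthetic-topograph generator (planar worm-like-chain
    backbones with end splays, central unwinding bubbles, terminal globules
    and optional antibody labels, rendered with probe-tip dilation, scan
    slant and noise), scan-line flattening by row- and column-wise median
    subtraction, automated molecule detection and selection, skeleton-graph
    tracing with an eight-segment feature decomposition, and per-molecule
    and population morphometrics (contour length, bubble size, normalized
    splay-to-splay distance, relative feature positions, conformational
    classes and group comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
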