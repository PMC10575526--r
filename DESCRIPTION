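Package: capnet
Title: Network-Level Analysis of Parafoveal Capillary Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for relating blood flow in human parafoveal capillaries to
    network-level properties of the surrounding microvascular tree. Builds a
    directed vascular graph from traced segment and junction tables,
    classifies capillaries by their supplying and collecting junctions,
    computes branch order and path distance from the feeding arteriole, fits
    junction exponents (generalized Murray's law) at bifurcations and
    confluences by brute-force grid search, localizes vessels in depth from
    OCT angiography slab stacks, estimates lumen diameters from straightened
    motion-contrast images with bootstrap confidence limits, summarizes
    pulsatile velocity traces, and reports Pearson correlations between
    network variables and flow parameters. A synthetic-data module generates
    networks, velocity traces, depth stacks and vessel images with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    tiff,
    EBImage
Suggests:
    readxl,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
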