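Package: osteoconnect
Title: Osteocyte Network Segmentation and Connectomics from Confocal Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Threshold-based semantic segmentation of osteocyte cell bodies
    and dendritic processes in 2D confocal-style greyscale images, conversion
    of segmentations into an osteocyte connectomics graph (osteocytes as
    nodes, dendrites as edges), network metrics (node counts, dead ends,
    connections per node, connection lengths and diameters), per-class Dice
    and IoU evaluation, an inverse component-size penalty for fragmented
    dendrite masks, and nonparametric two-group comparison of network
    metrics. Includes a seeded synthetic-scene generator that emulates
    confocal scans of osteocyte networks with known ground-truth masks and
    graphs, so the whole pipeline can be exercised and validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
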