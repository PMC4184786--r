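Package: rbtrack
Title: Growth and Mobility Analysis of ER Protein Aggregates from Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the growth and mobility of endoplasmic-reticulum protein
    aggregates (Russell bodies) in fluorescence microscopy. Implements two-colour
    pulse-chase morphometry (cluster diameters as the full width at half maximum
    of intensity profiles, and the relative size-increase statistic), single
    particle tracking (Laplacian-of-Gaussian spot detection and optimal bipartite
    frame-to-frame linking), time-averaged mean-square displacement curves with
    an anomalous-diffusion power-law fit MSD = 4*D*t^alpha, and population-level
    comparisons between treatment conditions. Ships a synthetic-data generator
    (fractional Brownian motion trajectories via Davies-Harte circulant
    embedding, and confocal-like two-channel images and movies with known ground
    truth) so the full pipeline is testable without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    clue,
    EBImage,
    tiff,
    jsonlite,
    withr,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
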