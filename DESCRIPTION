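Package: choroidseg
Title: Texture-Based Choroidal Boundary Segmentation for EDI-OCT B-Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Fully automatic segmentation of the choroid in enhanced depth
    imaging optical coherence tomography (EDI-OCT) B-scans. The retinal
    pigment epithelium (RPE) is traced by dynamic programming on inverted
    brightness, Bruch's membrane (BM) is located at the strongest intensity
    gradient below the RPE, and the choroid-sclera interface (CSI) is
    extracted by a multi-label graph cut driven by a Gaussian mixture model
    over undecimated Haar wavelet texture energies. Includes a seeded
    synthetic B-scan phantom generator with ground-truth boundaries,
    k-means / graph-cut / dynamic-programming comparison baselines, and
    signed/unsigned border positioning error metrics.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    igraph,
    withr,
    tiff,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
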