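Package: spheroflim
Title: Fluorescence Lifetime Metabolic Imaging Analysis of Tumor Spheroids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: End-to-end analysis of time-correlated single-photon-counting
    (TCSPC) fluorescence lifetime images of NAD(P)H and FAD autofluorescence
    from three-dimensional tumor spheroids. Provides a synthetic phantom
    generator with known ground-truth lifetime fields, binary-mask
    segmentation pipelines for intact spheroids and scattered migrating
    cells, constrained bi-exponential decay fitting with instrument-response
    convolution, computation of the fluorescence lifetime imaging redox
    ratio (FLIRR), kernel density estimation of FLIRR populations with an
    overlap index for condition comparisons, and spatial analysis of
    metabolic gradients by Euclidean-distance binning from the spheroid
    edge or centroid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
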