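Package: culmorph
Title: Quantitative Morphometry of Vascular Bundles in Bamboo Culm Cross-Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the distribution and morphology of vascular
    bundles in moso-bamboo culm cross-sections. Provides a synthetic
    cross-section generator with instance-labeled ground truth, a tile-based
    encoder-decoder (U-Net style) semantic segmenter with training and
    evaluation, first-principles region morphometry (moments, eccentricity,
    convex hull, extent), radial gradient profiling on a normalized
    epidermis-to-pith coordinate, internode-level group statistics (one-way
    ANOVA with Tukey HSD, Kruskal-Wallis with Dwass-Steel-Critchlow-Fligner
    post-hoc, compact letter displays), and a variational autoencoder for
    latent-space morphing of bundle shapes along the radial axis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    tiff,
    yaml,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    jsonlite,
    optparse
Config/testthat/edition: 3
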