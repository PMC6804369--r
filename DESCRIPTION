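Package: canopydyn
Title: Projected Canopy Height Phenotyping of Plant Populations Under
    Water Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Image-based screening of water-deficit response and recovery
    in dense plant canopies (e.g. barley populations) from side-view RGB
    images. Segments green vegetation, estimates projected canopy height
    with a line-descent stopping criterion, extracts drought and recovery
    kinetic traits from day-indexed height curves, computes chlorophyll
    fluorescence quenching yields and scalar physiological quantities
    (relative water content, substrate water status, antioxidant enzyme
    activities, per-dry-weight metabolite normalisation), and provides a
    synthetic image and curve generator with ground truth plus a
    multivariate reporting layer (correlations, PCA, group comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    png,
    tiff,
    yaml,
    jsonlite,
    igraph,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    multcomp,
    optparse
Config/testthat/edition: 3
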