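Package: starchseg
Title: Watershed Segmentation of Starch Granules with Oversegment Merging
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments dark, round starch granules in bright-field microscopy
    images and reports their position, shape and size. Granules are separated
    from the background by an iterative class-mean-midpoint (ISODATA)
    threshold, touching and overlapping granules are split by Meyer watershed
    flooding of a chamfer distance map, watershed oversegments are identified
    by low roundness and by the absence of a gradient-vector-flow critical
    point near the segment centre, and identified oversegments are merged back
    into their parent granules by weighted fuzzy c-means clustering. Includes
    a seeded synthetic-scene generator with ground-truth labels for
    validation, CSV morphometry reports, label-map and overlay output, and a
    small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
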