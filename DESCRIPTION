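Package: spatialClonality
Title: Spatial Clonality Analysis for Multicolor Fate-Mapping Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies local clonal structure in multicolor (Confetti/Brainbow)
    fate-mapping images of tissue sections. Converts multichannel fluorescence
    images into marked spatial point patterns, computes the nearest-neighbour
    mingling index and smoothed color probability maps, merges adjacent
    same-color Voronoi tiles into clonal clusters, and compares both statistics
    against randomized Poisson (complete spatial randomness) null ensembles
    with paired tests across samples. Includes a synthetic-data generator for
    random and clustered clonal point patterns and a renderer that turns
    patterns into noisy multichannel images, so the full pipeline is testable
    without microscopy data. Also provides thresholded area-fraction
    quantification for single-reporter fate-mapping sections.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    deldir,
    RANN,
    EBImage,
    igraph,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
biocViews: Spatial, SingleCell, CellBiology, Visualization
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'domain.R'
    'experiment.R'
    'geometry-utils.R'
    'imaging.R'
    'io.R'
    'mingling.R'
    'null-inference.R'
    'pattern.R'
    'pipeline.R'
    'report.R'
    'spatialClonality-package.R'
    'synthetic.R'
    'voronoi.R'
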