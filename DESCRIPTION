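Package: geofeat
Title: Geometry-Aware Container for Spatial Transcriptomics Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A single container aligning a gene count matrix with vector
    geometry layers (spot/cell centroids, segmentation polygons, per-gene
    transcript multipoints, tissue annotations), spatial neighborhood graphs
    (k nearest neighbors, distance bands, Delaunay triangulation with Gabriel
    pruning, queen polygon contiguity), per-location local statistics, and
    extent-registered raster images, all in one Cartesian coordinate system.
    Supports geometry-synchronized subsetting, affine transforms of the whole
    object, cropping with spatial predicates, predicate joins between layers,
    aggregation of cells and transcript spots into new count matrices over
    arbitrary polygons or regular square/hexagonal grids, Visium-style
    directory readers, GeoParquet geometry serialization, and a
    language-agnostic on-disk layout for whole objects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Matrix,
    sp,
    deldir,
    jsonlite,
    arrow,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
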