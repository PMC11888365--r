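# geofeat

Spatial transcriptomics assays measure gene expression *somewhere*: at
barcoded spots on a slide, in segmented cells, at individual transcript
molecules. Analyzing them means constantly juggling a count matrix, the
vector geometry of the locations, tissue annotations, neighborhood graphs for
spatial statistics, and histology images — and keeping all of these aligned
while you filter, crop, transform, or re-bin the data.

`geofeat` puts everything in one container and makes the bookkeeping
automatic:

- **`SpatialFeatureContainer`** — assays (`n_features x n_locations`),
  per-column geometries (centroids, segmentation polygons), per-row
  geometries (transcript multipoints), free-standing annotation layers
  (tissue boundary, regions), spatial graphs, per-location local statistics,
  and extent-registered raster images, all in one 2-D Cartesian y-up frame
  with explicit units.
- **Synchronized subsetting** — `sfc[i, j]` filters every aligned part
  together; graphs are restricted to surviving nodes (row-standardized
  weights re-normalized) and flagged as subsetted.
- **Geometry operations** — spatial predicates (`intersects`, `contains`,
  `within`, `touches`), predicate joins between layers (`relate`), cropping
  with clipping or keep-whole annotation handling, per-location annotation
  summaries, splitting by region.
- **Affine transforms** — whole-container translate / scale / rotate /
  mirror / transpose with images kept co-registered; axis-aligned image
  transforms are exact pixel permutations, general ones resample.
- **Aggregation** — square or flat-topped hexagonal grids and arbitrary
  polygon bins; cells or raw transcript spots are re-binned into new count
  matrices with exact conservation of totals when the bins cover the data.
- **Graphs** — k nearest neighbors, inclusive distance bands, Delaunay
  triangulation with Gabriel pruning, queen polygon contiguity; binary or
  row-standardized weights.
- **Images** — TIFF/PNG with mandatory extents, lazy loading with a queued
  operation pipeline that is bit-exact against eager evaluation, zonal
  statistics under polygons, cropping and block-average downsampling.
- **I/O** — a Visium-style (Space Ranger >= 2.0) directory reader, a
  transcript-spot CSV reader with GeoParquet caching, GeoParquet geometry
  serialization (bit-exact WKB coordinates), and a language-agnostic on-disk
  layout for whole containers (MatrixMarket + CSV + GeoParquet + JSON +
  16-bit TIFF) with full-precision round trips.

## Quick tour

```r
library(geofeat)

# a deterministic, fully populated synthetic dataset
sfc <- synth_dataset(n_cells = 40, n_genes = 12, seed = 1)
sfc
#> SpatialFeatureContainer: 12 features x 40 locations [micron]
#>   assays: counts
#>   col geometries: centroids, cellSeg
#>   row geometries: txSpots
#>   annot geometries: tissue, regions
#>   images: gradient

# neighborhood graph over cell centroids, row-standardized
sfc <- find_spatial_graph(sfc, "col", "centroids", "knn", list(k = 5),
                          style = "row_standardized")

# aggregate cells onto a hexagonal grid; totals are conserved exactly
grid <- make_grid(c(0, 0, 100, 100), "hex", cellsize = 25)
agg <- aggregate_cells(sfc, grid)
all(rowSums(get_assay(agg)) == rowSums(get_assay(sfc)))
#> [1] TRUE

# crop to a window: columns, geometries, graphs, images stay in sync
crop(sfc, c(25, 25, 75, 75), "centroids", "intersects")
#> SpatialFeatureContainer: 12 features x 11 locations [micron]
#>   assays: counts
#>   col geometries: centroids, cellSeg
#>   row geometries: txSpots
#>   annot geometries: tissue, regions
#>   col graphs: knn
#>   images: gradient

# zonal statistics: mean image intensity under each cell polygon
head(extract_pixels(get_image(sfc, "gradient"),
                    get_geometry(sfc, "col", "cellSeg"), "mean"))
#> [1] 0.5302 0.4850 0.6504 0.7439 0.3732 0.8322

# read a Visium-style directory (here a generated fixture)
d <- tempfile(); synth_visium_dir(6, 10, seed = 7, outdir = d)
vis <- read_visium_like(d)

# save / load the whole container, full precision
save_container(sfc, "my_container")
identical(get_assay(load_container("my_container")), get_assay(sfc))
#> [1] TRUE
```

See the vignette source in `vignettes/geofeat-methods.Rmd` for the data
model, coordinate and serialization conventions, and the reasoning behind
the numerical choices (boundary tie-breaking, hex grid convention, convex
clipping, the 16-bit image round-trip contract).

## Command line

A thin CLI ships in `inst/cli/geofeat.R`:

```sh
Rscript inst/cli/geofeat.R fixtures visium -o tmpdir --seed 7
Rscript inst/cli/geofeat.R convert visium tmpdir -o container_dir
Rscript inst/cli/geofeat.R crop container_dir -o cropped --bbox 100,100,500,500
Rscript inst/cli/geofeat.R aggregate container_dir -o binned --cellsize 200 --kind hex
Rscript inst/cli/geofeat.R transform container_dir -o rotated --kind rotate --angle 90
Rscript inst/cli/geofeat.R spots2parquet spots.csv
```

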