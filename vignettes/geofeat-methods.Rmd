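---
title: "geofeat: model, conventions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{geofeat: model, conventions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(geofeat)
```

## The data model

Spatial transcriptomics measurements pair a gene-by-location count matrix
with geometric context: where each spot or cell sits, what shape it has,
which transcripts were detected where, and what the surrounding tissue looks
like. `geofeat` keeps all of that in one S4 object, the
`SpatialFeatureContainer`, whose parts are aligned to the two matrix axes:

* **assays** — numeric matrices, `n_features x n_locations`. The first assay
  is named `counts` and must be non-negative.
* **col geometries** — one geometry per matrix *column* (location): spot or
  cell centroids (`POINT`), segmentation polygons (`POLYGON`). Row `i` of a
  col layer always belongs to matrix column `i`.
* **row geometries** — one geometry per matrix *row* (feature): typically a
  `MULTIPOINT` of every detected transcript of that gene.
* **annot geometries** — free-standing annotation layers (tissue boundary,
  histological regions); not aligned to either axis.
* **col/annot graphs** — spatial neighborhood graphs over locations or over
  an annotation layer.
* **local results** — per-location outputs of local spatial statistics,
  keyed by statistic then feature.
* **images** — raster layers registered to the coordinate system by an
  extent.

Everything lives in a single 2-D Cartesian, y-up coordinate frame with a
stated unit string (`"micron"`, `"full_res_pixel"`, ...). The central
invariant is *synchronized subsetting*: `sfc[i, j]` (or
`subset_container()`) filters assays, metadata, geometry layers, graphs, and
local results consistently, so row `k` of any col layer always describes
matrix column `k`. Subsetting composes: filtering in two steps equals
filtering once with the composed index.

### Geometries without a geometry stack

Geometries use a minimal simple-features representation: a `POINT` is a
length-2 numeric; `MULTIPOINT`/`LINESTRING` are n-by-2 matrices; a `POLYGON`
is a list of closed rings (first exterior, the rest holes, even-odd
interpretation); a `MULTIPOLYGON` is a list of polygons. Predicates
(`intersects`, `contains`, `within`, `touches`) follow standard
simple-features semantics and are implemented from segment/point primitives:
point-in-polygon tests distinguish interior (1), boundary (2), and exterior
(0), so boundary cases are decided explicitly rather than by floating-point
luck.

## Images and registration

An image is a pixel matrix (row 1 on top) plus an extent
`(xmin, ymin, xmax, ymax)`. The center of pixel `(r, c)` sits at
`x = xmin + (c - 0.5) * w / ncols`, `y = ymax - (r - 0.5) * h / nrows`.
Because the frame is y-up while pixel rows grow downward, the top pixel row
corresponds to `ymax`.

`LazyImage` defers pixel reads: only the file header is parsed (dimensions
and channel count), and axis-aligned operations (mirror, transpose) are
queued and applied once at `materialize()`. The queue is defined to be
bit-exact against eager evaluation: both paths end in the same pixel-array
permutation.

### Serialization precision contract

* Counts are written as MatrixMarket text with 17 significant digits, which
  round-trips IEEE doubles exactly; local results use `%.17g` CSV; graph
  weights use 17-digit JSON. Geometry coordinates travel as WKB inside
  GeoParquet, which is bit-exact by construction.
* Images are written as 16-bit lossless TIFF. Values round-trip bit-exactly
  **iff** they lie on the 16-bit grid `k / 65535`. Anything read from an 8-
  or 16-bit file is already on that grid (`k / 255` equals `257 k / 65535`
  exactly in double arithmetic); synthetic images should be pre-quantized
  with `round(x * 65535) / 65535` if exact round trips matter.

## Parameter conventions and defaults

* **kNN graphs** (`graph_knn`): `k` nearest Euclidean neighbors, exact
  distance ties broken toward the lower point index so results are
  deterministic. The directed neighbor sets are symmetrized with the
  `"union"` rule by default (edge if either point names the other);
  `"mutual"` keeps only reciprocated pairs. Binary weights;
  `row_standardize()` converts to directed `1/deg(i)` weights that sum to 1
  per non-isolated node and are re-normalized after subsetting.
* **Distance bands** (`graph_distance`): inclusive threshold
  (`d <= d_max`), isolated nodes allowed.
* **Delaunay/Gabriel** (`graph_delaunay`): triangulation edges; Gabriel
  pruning keeps edge `(i, j)` iff the *open* disk with diameter `ij`
  contains no other point, which guarantees Gabriel ⊆ Delaunay.
  Collinear inputs are rejected explicitly.
* **Queen contiguity** (`graph_contiguity`): polygons are neighbors iff
  their boundaries come within `snap` (default `1e-9`) of each other;
  corner contact counts.
* **Grids** (`make_grid`): square grids anchor at the extent's lower-left
  corner and use the ceiling rule, so cells may overhang the extent but
  always cover it. Hex grids are flat-topped with `cellsize` equal to the
  horizontal center-to-center spacing (circumradius `2 * cellsize / 3`,
  vertical pitch `sqrt(3)` times the circumradius, odd columns offset by
  half a pitch).
* **Point-to-bin assignment**: a point on a shared bin boundary is assigned
  once, to the lowest bin index, so aggregation never double-counts. With
  `fun = sum`, empty bins give 0 and totals are conserved whenever the bins
  cover every assignment point; other summary functions give `NA` on empty
  bins.
* **Cropping** (`crop`): locations are kept by a predicate between their
  col geometry and the query (`intersects`, `contains_in`, `covered_by`);
  annotation layers are either geometrically clipped (`annot_op = "clip"`)
  or kept whole when intersecting.
* **Visium-style reading** (`read_visium_like`): expects the
  Space Ranger >= 2.0 layout and rejects the older headerless
  `tissue_positions_list.csv` dialect by name. Coordinates are full-res
  pixels; by default pixel rows are flipped to y-up using the full-res
  height inferred from the low-res PNG and `tissue_lowres_scalef`, keeping
  spots and image co-registered. Spot polygons are regular 32-gons — their
  area falls short of the true disc by `1 - (32 / (2 * pi)) * sin(2 * pi / 32)`,
  about 0.64%, kept below a 1% error budget.

## Numerical choices worth knowing

* **Convex clipping only.** Geometric intersection for `annot_op = "clip"`
  uses Sutherland–Hodgman, which is only correct for convex query windows
  (the common case: bounding boxes). Non-convex queries are rejected with
  advice to use `keep_whole`; this avoids shipping a subtly wrong general
  polygon clipper.
* **Affine transforms.** `affine_named()` builds the usual maps; pivoting
  kinds default to `center = "bbox"`, a *deferred* pivot resolved against
  the container bounding box at application time so the data footprint stays
  in place. Reflections reverse ring orientation; `transform_layer` restores
  counter-clockwise exteriors.
* **Image resampling.** Axis-aligned transforms (diagonal or anti-diagonal
  linear part) are pure pixel permutations — no interpolation, bit-exact.
  General affines resample by inverse mapping onto the transformed extent's
  bounding box at approximately the input pixel density (scaled by
  `sqrt(|det M|)`), bilinear by default.
* **Row-standardized graph storage.** Binary graphs store each undirected
  edge once (`i < j`); row-standardized graphs store directed edges both
  ways because weights `1/deg(i)` are asymmetric.
* **Interchange format.** Graph JSON uses 0-based node indices on disk (the
  common convention outside R) and converts back on load.

## The synthetic generators

`synth_dataset()` builds a fully populated container: uniform centroids,
bounded-Voronoi cell polygons, per-gene Poisson counts with log-uniform
means on `[0.1, 20]`, transcript multipoints scattered
Gaussian (sd = 2% of the extent width) around their cell centroid — so spot
counts equal matrix counts *exactly* — a convex-hull tissue boundary
buffered outward, left/right region annotations, and a smooth gradient
image pre-quantized to the 16-bit grid. `synth_visium_dir()` writes a
complete Space Ranger-style directory with a hex-packed spot array and a
diagonal-gradient PNG whose value at any point is known in closed form,
which is what makes reader/registration tests sharp.

These generators are *fixtures*, not biological simulations: counts are
independent Poisson draws with no spatial covariance (apart from the
optional `region_fold_change` knob boosting half the genes on the right
half of the extent), cell shapes are Voronoi cells rather than realistic
morphologies, and images are smooth gradients rather than histology. They
are deterministic pure functions of their arguments — the RNG state is
saved, seeded, and restored — so every test and example is reproducible
bit-for-bit.

## A worked example

```{r example}
sfc <- synth_dataset(n_cells = 40, n_genes = 12, seed = 1)
sfc

# neighborhood graph over cell centroids, row-standardized
sfc <- find_spatial_graph(sfc, "col", "centroids", "knn", list(k = 5),
                          style = "row_standardized")
Matrix::rowSums(graph_weights(get_graph(sfc, "col", "knn")))[1:5]

# aggregate cells onto a hexagonal grid; totals are conserved
grid <- make_grid(c(0, 0, 100, 100), "hex", cellsize = 25)
agg <- aggregate_cells(sfc, grid)
all(rowSums(get_assay(agg)) == rowSums(get_assay(sfc)))

# crop to a window: columns, geometries, graphs, and images stay in sync
cropped <- crop(sfc, c(25, 25, 75, 75), "centroids", "intersects")
cropped

# zonal statistics: mean image intensity under each cell polygon
head(extract_pixels(get_image(sfc, "gradient"),
                    get_geometry(sfc, "col", "cellSeg"), "mean"))

# round trip through the on-disk layout
d <- tempfile("sfc")
save_container(sfc, d)
identical(get_assay(load_container(d)), get_assay(sfc))
```
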