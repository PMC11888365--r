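#' @import methods
NULL

#' Axis-aligned spatial extent
#'
#' The rectangle `(xmin, ymin, xmax, ymax)` registering geometry layers and
#' raster images to a common Cartesian coordinate system (x rightward,
#' y upward; image pixel row 1 is the TOP row, at `y = ymax`).
#'
#' @slot xmin,ymin,xmax,ymax numeric scalars with `xmin < xmax`,
#'   `ymin < ymax`.
#' @export
setClass("SpatialExtent",
  representation(xmin = "numeric", ymin = "numeric",
                 xmax = "numeric", ymax = "numeric"))

setValidity("SpatialExtent", function(object) {
  v <- c(object@xmin, object@ymin, object@xmax, object@ymax)
  if (length(v) != 4L || !all(is.finite(v))) return("extent must be 4 finite numbers")
  if (object@xmin >= object@xmax) return("xmin must be < xmax")
  if (object@ymin >= object@ymax) return("ymin must be < ymax")
  TRUE
})

#' Create a spatial extent
#'
#' @param xmin,ymin,xmax,ymax rectangle bounds, or pass a numeric vector
#'   `c(xmin, ymin, xmax, ymax)` as `xmin`.
#' @return a [SpatialExtent-class] object.
#' @export
spatial_extent <- function(xmin, ymin = NULL, xmax = NULL, ymax = NULL) {
  if (is.null(ymin) && length(xmin) == 4L) {
    v <- as.numeric(xmin)
    return(new("SpatialExtent", xmin = v[1L], ymin = v[2L],
               xmax = v[3L], ymax = v[4L]))
  }
  new("SpatialExtent", xmin = as.numeric(xmin), ymin = as.numeric(ymin),
      xmax = as.numeric(xmax), ymax = as.numeric(ymax))
}

as_extent_vec <- function(e) {
  if (is(e, "SpatialExtent")) return(c(e@xmin, e@ymin, e@xmax, e@ymax))
  if (is.numeric(e) && length(e) == 4L) return(as.numeric(e))
  stop("expected a SpatialExtent or numeric c(xmin, ymin, xmax, ymax)")
}

as_spatial_extent <- function(e) {
  if (is(e, "SpatialExtent")) e else spatial_extent(as_extent_vec(e))
}

#' 2-D affine transform
#'
#' Applied to a point as `p' = M p + v`. Named transforms created with a
#' deferred pivot (`center = "bbox"`) carry the recipe instead of the matrix
#' and are resolved against a container's bounding box by
#' [transform_container()] or [resolve_transform()].
#'
#' @slot M 2x2 linear part (invertible once resolved).
#' @slot v length-2 translation.
#' @slot resolved logical; `FALSE` for a deferred-pivot named transform.
#' @slot kind the named-transform kind, or `"matrix"`.
#' @slot params named-transform parameters (for deferred resolution).
#' @export
setClass("AffineTransform",
  representation(M = "matrix", v = "numeric", resolved = "logical",
                 kind = "character", params = "list"))

setValidity("AffineTransform", function(object) {
  if (!identical(dim(object@M), c(2L, 2L))) return("M must be 2x2")
  if (length(object@v) != 2L) return("v must have length 2")
  if (object@resolved) {
    if (!all(is.finite(object@M)) || !all(is.finite(object@v)))
      return("non-finite transform")
    if (abs(det(object@M)) < 1e-12) return("transform is not invertible (det(M) ~ 0)")
  }
  TRUE
})

#' Simple-features geometry layer
#'
#' A homogeneous list of 2-D geometries plus an attribute table with one row
#' per geometry. See [geometry-primitives] for the geometry structures.
#'
#' @slot geoms list of geometry structures.
#' @slot geom_type one of POINT, MULTIPOINT, LINESTRING, POLYGON,
#'   MULTIPOLYGON.
#' @slot attrs data.frame with `length(geoms)` rows.
#' @export
setClass("GeometryLayer",
  representation(geoms = "list", geom_type = "character", attrs = "data.frame"))

setValidity("GeometryLayer", function(object) {
  if (length(object@geom_type) != 1L || !object@geom_type %in% GEOM_TYPES)
    return(paste("geom_type must be one of", paste(GEOM_TYPES, collapse = ", ")))
  if (nrow(object@attrs) != length(object@geoms))
    return("attribute table must have one row per geometry")
  for (g in object@geoms) {
    msg <- validate_geom(g, object@geom_type)
    if (!is.null(msg)) return(msg)
  }
  TRUE
})

#' Create a geometry layer
#'
#' @param geoms list of geometry structures, all of type `type`.
#' @param type geometry type string.
#' @param attrs data.frame of per-geometry attributes (default: empty columns).
#' @return a [GeometryLayer-class].
#' @export
geometry_layer <- function(geoms, type, attrs = NULL) {
  if (is.null(attrs)) {
    attrs <- data.frame(row.names = seq_along(geoms))
  }
  new("GeometryLayer", geoms = unname(geoms), geom_type = type,
      attrs = as.data.frame(attrs))
}

#' Number of geometries in a layer
#' @param layer a [GeometryLayer-class].
#' @export
n_geometries <- function(layer) length(layer@geoms)

#' Spatial neighborhood graph
#'
#' Adjacency over the rows of one geometry layer. Binary graphs store each
#' unordered pair once (`i < j`, weight 1, `directed = FALSE`);
#' row-standardized graphs store both directions with weight `1/deg(i)`
#' (`directed = TRUE`), so each node's outgoing weights sum to 1.
#'
#' @slot n_nodes number of nodes.
#' @slot edges data.frame with integer columns `i`, `j` (1-based) and numeric
#'   `weight`; no self loops.
#' @slot style `"binary"` or `"row_standardized"`.
#' @slot directed whether `edges` lists both directions.
#' @slot method_meta list: `method`, `params`, `layer` (referenced layer
#'   name or `NA`), `subsetted` flag; kNN/distance methods also record the
#'   edge distances here.
#' @export
setClass("SpatialGraph",
  representation(n_nodes = "integer", edges = "data.frame",
                 style = "character", directed = "logical",
                 method_meta = "list"))

setValidity("SpatialGraph", function(object) {
  e <- object@edges
  if (!all(c("i", "j", "weight") %in% names(e)))
    return("edges must have columns i, j, weight")
  if (nrow(e) > 0L) {
    if (any(e$i < 1L | e$i > object@n_nodes | e$j < 1L | e$j > object@n_nodes))
      return("edge endpoints out of range")
    if (any(e$i == e$j)) return("self loops are not allowed")
    if (!object@directed && any(e$i >= e$j))
      return("undirected edges must be stored once with i < j")
    key <- paste(e$i, e$j)
    if (anyDuplicated(key)) return("duplicate edges")
  }
  if (!object@style %in% c("binary", "row_standardized"))
    return("style must be binary or row_standardized")
  if (object@style == "row_standardized" && object@n_nodes > 0L && nrow(e) > 0L) {
    s <- tapply(e$weight, e$i, sum)
    if (any(abs(s - 1) > 1e-9))
      return("row-standardized outgoing weights must sum to 1 per node")
  }
  TRUE
})

spatial_graph <- function(n_nodes, edges, style = "binary", directed = FALSE,
                          method_meta = list()) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(i = integer(0), j = integer(0), weight = numeric(0))
  }
  mm <- utils::modifyList(
    list(method = NA_character_, params = list(), layer = NA_character_,
         subsetted = FALSE),
    method_meta)
  edges <- as.data.frame(edges)
  rownames(edges) <- NULL
  new("SpatialGraph", n_nodes = as.integer(n_nodes),
      edges = edges, style = style, directed = directed,
      method_meta = mm)
}

#' Extent-registered raster image (virtual)
#'
#' Pixel column `c` (1-based) has center `x = xmin + (c - 0.5) * w / ncols`;
#' pixel row `r` has center `y = ymax - (r - 0.5) * h / nrows` (row 1 is the
#' top row). Two flavors exist: [MemoryImage-class] holds the pixel array;
#' [LazyImage-class] holds a file path, cached dimensions, and a queue of
#' pending axis-aligned operations, answering metadata queries without
#' loading pixels.
#'
#' @slot extent the image's [SpatialExtent-class].
#' @export
setClass("ImageLayer", representation("VIRTUAL", extent = "SpatialExtent"))

#' @rdname ImageLayer-class
#' @slot pixels numeric array, `nrow x ncol` (grayscale) or
#'   `nrow x ncol x channels`, values typically in `[0, 1]`.
#' @export
setClass("MemoryImage", contains = "ImageLayer",
  representation(pixels = "array"))

setValidity("MemoryImage", function(object) {
  d <- dim(object@pixels)
  if (!length(d) %in% c(2L, 3L)) return("pixels must be a 2-D or 3-D array")
  if (any(d[1:2] < 1L)) return("image must have at least one pixel")
  TRUE
})

#' @rdname ImageLayer-class
#' @slot path source file (PNG or TIFF).
#' @slot width,height,channels cached dimensions (AFTER applying `queue`).
#' @slot queue character vector of pending ops among `mirror_h`, `mirror_v`,
#'   `transpose`, applied in order at materialization.
#' @export
setClass("LazyImage", contains = "ImageLayer",
  representation(path = "character", width = "integer", height = "integer",
                 channels = "integer", queue = "character"))

#' Spatial feature container
#'
#' One object aligning assays (feature x location matrices), feature and
#' location metadata, named geometry layers on three axes (col = locations,
#' row = features, annot = free annotations such as tissue boundaries),
#' spatial neighborhood graphs, per-location local statistics, and
#' extent-registered images — all in one Cartesian coordinate frame.
#' Subsetting rows/columns keeps every aligned component synchronized.
#'
#' @slot assays named list of numeric matrices, all `n_features x
#'   n_locations`; the `"counts"` assay, when present, is non-negative.
#' @slot row_meta data.frame with `n_features` rows (global per-feature
#'   statistics such as Moran's I live here as plain columns).
#' @slot col_meta data.frame with `n_locations` rows.
#' @slot col_geometries,row_geometries,annot_geometries named lists of
#'   [GeometryLayer-class]; col layers have `n_locations` rows (row i of the
#'   layer belongs to matrix column i), row layers `n_features` rows, annot
#'   layers any number.
#' @slot col_graphs,annot_graphs named lists of [SpatialGraph-class]; a col
#'   graph has `n_locations` nodes, an annot graph as many nodes as its
#'   referenced annot layer has rows.
#' @slot local_results two-level named list, statistic -> feature -> matrix
#'   with `n_locations` rows and named stat columns.
#' @slot images named list of [ImageLayer-class].
#' @slot units free unit string, e.g. `"full_res_pixel"` or `"micron"`.
#' @slot metadata free-form list (e.g. aggregation provenance).
#' @export
setClass("SpatialFeatureContainer",
  representation(assays = "list", row_meta = "data.frame",
                 col_meta = "data.frame",
                 col_geometries = "list", row_geometries = "list",
                 annot_geometries = "list",
                 col_graphs = "list", annot_graphs = "list",
                 local_results = "list", images = "list",
                 units = "character", metadata = "list"))

setValidity("SpatialFeatureContainer", function(object) {
  if (length(object@assays) == 0L) return("at least one assay is required")
  d <- dim(object@assays[[1L]])
  for (nm in names(object@assays)) {
    a <- object@assays[[nm]]
    if (!identical(dim(a), d))
      return(sprintf("assay '%s' dimensions disagree with the first assay", nm))
  }
  if ("counts" %in% names(object@assays)) {
    cnt <- object@assays[["counts"]]
    if (length(cnt) > 0L && isTRUE(any(cnt < 0, na.rm = TRUE)))
      return("counts assay must be non-negative")
  }
  nf <- d[1L]; nl <- d[2L]
  if (nrow(object@row_meta) != nf)
    return(sprintf("row_meta has %d rows but assays have %d features (rows)",
                   nrow(object@row_meta), nf))
  if (nrow(object@col_meta) != nl)
    return(sprintf("col_meta has %d rows but assays have %d locations (columns)",
                   nrow(object@col_meta), nl))
  for (nm in names(object@col_geometries)) {
    if (n_geometries(object@col_geometries[[nm]]) != nl)
      return(sprintf("col geometry layer '%s' has %d rows, expected n_locations = %d",
                     nm, n_geometries(object@col_geometries[[nm]]), nl))
  }
  for (nm in names(object@row_geometries)) {
    if (n_geometries(object@row_geometries[[nm]]) != nf)
      return(sprintf("row geometry layer '%s' has %d rows, expected n_features = %d",
                     nm, n_geometries(object@row_geometries[[nm]]), nf))
  }
  for (nm in names(object@col_graphs)) {
    if (object@col_graphs[[nm]]@n_nodes != nl)
      return(sprintf("col graph '%s' has %d nodes, expected n_locations = %d",
                     nm, object@col_graphs[[nm]]@n_nodes, nl))
  }
  for (nm in names(object@annot_graphs)) {
    g <- object@annot_graphs[[nm]]
    ref <- g@method_meta$layer
    if (!is.na(ref) && ref %in% names(object@annot_geometries)) {
      need <- n_geometries(object@annot_geometries[[ref]])
      if (g@n_nodes != need)
        return(sprintf("annot graph '%s' has %d nodes but layer '%s' has %d rows",
                       nm, g@n_nodes, ref, need))
    }
  }
  for (st in names(object@local_results)) {
    for (ft in names(object@local_results[[st]])) {
      m <- object@local_results[[st]][[ft]]
      if (nrow(m) != nl)
        return(sprintf("local result (%s, %s) has %d rows, expected n_locations = %d",
                       st, ft, nrow(m), nl))
    }
  }
  for (nm in names(object@images)) {
    if (!is(object@images[[nm]], "ImageLayer"))
      return(sprintf("image '%s' is not an ImageLayer", nm))
  }
  TRUE
})
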