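#' Create a spatial feature container
#'
#' Builds a container from a counts matrix and its feature/location metadata;
#' geometry layers, graphs, local results, and images start empty and are
#' attached with their setters.
#'
#' @param counts numeric matrix, `n_features x n_locations`, non-negative.
#' @param col_meta data.frame with one row per location (matrix column).
#' @param row_meta data.frame with one row per feature (matrix row).
#' @param units coordinate unit string, e.g. `"micron"` or `"full_res_pixel"`.
#' @return a [SpatialFeatureContainer-class].
#' @examples
#' cnt <- matrix(rpois(12, 2), 3, 4)
#' sfc <- new_container(cnt, data.frame(barcode = paste0("b", 1:4)),
#'                      data.frame(gene = paste0("g", 1:3)))
#' n_locations(sfc)
#' @export
new_container <- function(counts, col_meta, row_meta, units = "unit") {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  col_meta <- as.data.frame(col_meta)
  row_meta <- as.data.frame(row_meta)
  if (nrow(col_meta) != ncol(counts)) {
    stop(sprintf(paste0("location axis mismatch: counts has %d columns but ",
                        "col_meta has %d rows"), ncol(counts), nrow(col_meta)))
  }
  if (nrow(row_meta) != nrow(counts)) {
    stop(sprintf(paste0("feature axis mismatch: counts has %d rows but ",
                        "row_meta has %d rows"), nrow(counts), nrow(row_meta)))
  }
  new("SpatialFeatureContainer",
      assays = list(counts = counts), row_meta = row_meta, col_meta = col_meta,
      col_geometries = list(), row_geometries = list(),
      annot_geometries = list(), col_graphs = list(), annot_graphs = list(),
      local_results = list(), images = list(), units = units,
      metadata = list())
}

#' Container dimensions and metadata accessors
#'
#' @param c a [SpatialFeatureContainer-class].
#' @param name assay name.
#' @name container-accessors
#' @export
n_features <- function(c) nrow(c@assays[[1L]])

#' @rdname container-accessors
#' @export
n_locations <- function(c) ncol(c@assays[[1L]])

#' @rdname container-accessors
#' @export
get_assay <- function(c, name = "counts") {
  if (!name %in% names(c@assays)) stop("no assay named '", name, "'")
  c@assays[[name]]
}

#' @rdname container-accessors
#' @param value matrix of the same dimensions as the existing assays.
#' @export
set_assay <- function(c, name, value) {
  value <- as.matrix(value)
  storage.mode(value) <- "double"
  c@assays[[name]] <- value
  validObject(c)
  c
}

#' @rdname container-accessors
#' @export
col_meta <- function(c) c@col_meta

#' @rdname container-accessors
#' @export
row_meta <- function(c) c@row_meta

#' @rdname container-accessors
#' @export
container_units <- function(c) c@units

geom_slot <- function(axis) {
  switch(axis, col = "col_geometries", row = "row_geometries",
         annot = "annot_geometries",
         stop("axis must be one of 'col', 'row', 'annot'"))
}

#' Get / set a geometry layer
#'
#' Layers on the `col` axis must have exactly `n_locations` geometries (row i
#' of the layer belongs to matrix column i), layers on the `row` axis exactly
#' `n_features`; `annot` layers are unconstrained. Setting an existing name
#' replaces the layer.
#'
#' @param c a [SpatialFeatureContainer-class].
#' @param axis `"col"`, `"row"`, or `"annot"`.
#' @param name layer name.
#' @param layer a [GeometryLayer-class].
#' @return `set_geometry` returns the updated container; `get_geometry` the
#'   layer.
#' @export
set_geometry <- function(c, axis, name, layer) {
  axis <- match.arg(axis, c("col", "row", "annot"))
  stopifnot(is(layer, "GeometryLayer"))
  need <- switch(axis, col = n_locations(c), row = n_features(c), annot = NA)
  if (!is.na(need) && n_geometries(layer) != need) {
    stop(sprintf("%s geometry layer '%s' has %d geometries but the container has %d %s",
                 axis, name, n_geometries(layer), need,
                 if (axis == "col") "locations" else "features"))
  }
  slot(c, geom_slot(axis))[[name]] <- layer
  c
}

#' @rdname set_geometry
#' @export
get_geometry <- function(c, axis, name) {
  axis <- match.arg(axis, c("col", "row", "annot"))
  layers <- slot(c, geom_slot(axis))
  if (!name %in% names(layers)) {
    stop(sprintf("no %s geometry layer named '%s' (available: %s)", axis, name,
                 if (length(layers)) paste(names(layers), collapse = ", ")
                 else "<none>"))
  }
  layers[[name]]
}

#' @rdname set_geometry
#' @export
geometry_names <- function(c, axis) {
  names(slot(c, geom_slot(axis)))
}

graph_slot <- function(scope) {
  switch(scope, col = "col_graphs", annot = "annot_graphs",
         stop("graph scope must be 'col' or 'annot'"))
}

#' Get / set a spatial graph on the container
#'
#' @param c a [SpatialFeatureContainer-class].
#' @param scope `"col"` (graph over locations) or `"annot"` (graph over an
#'   annotation layer).
#' @param name graph name.
#' @param graph a [SpatialGraph-class].
#' @export
set_graph <- function(c, scope, name, graph) {
  scope <- match.arg(scope, c("col", "annot"))
  stopifnot(is(graph, "SpatialGraph"))
  slot(c, graph_slot(scope))[[name]] <- graph
  validObject(c)
  c
}

#' @rdname set_graph
#' @export
get_graph <- function(c, scope, name) {
  scope <- match.arg(scope, c("col", "annot"))
  gs <- slot(c, graph_slot(scope))
  if (!name %in% names(gs)) stop("no ", scope, " graph named '", name, "'")
  gs[[name]]
}

#' Get / set an image layer
#' @param c a [SpatialFeatureContainer-class].
#' @param name image name.
#' @param img an [ImageLayer-class].
#' @export
set_image <- function(c, name, img) {
  stopifnot(is(img, "ImageLayer"))
  c@images[[name]] <- img
  c
}

#' @rdname set_image
#' @export
get_image <- function(c, name) {
  if (!name %in% names(c@images)) stop("no image named '", name, "'")
  c@images[[name]]
}

#' Store / retrieve a per-location local statistic
#'
#' Local spatial statistics (e.g. local Moran's I) return one value (or a few
#' named fields) per location for a given feature; they are kept in a
#' two-level map keyed by statistic then feature, each entry a matrix with
#' `n_locations` rows. Global per-feature statistics belong in `row_meta`
#' columns instead.
#'
#' @param c a [SpatialFeatureContainer-class].
#' @param statistic statistic name, e.g. `"localmoran"`.
#' @param feature feature name.
#' @param values matrix with `n_locations` rows and named columns (e.g.
#'   `"stat"`, `"p_value"`).
#' @export
set_local_result <- function(c, statistic, feature, values) {
  values <- as.matrix(values)
  if (nrow(values) != n_locations(c)) {
    stop(sprintf("local result (%s, %s) has %d rows but the container has %d locations",
                 statistic, feature, nrow(values), n_locations(c)))
  }
  if (is.null(c@local_results[[statistic]])) {
    c@local_results[[statistic]] <- list()
  }
  c@local_results[[statistic]][[feature]] <- values
  c
}

#' @rdname set_local_result
#' @export
get_local_result <- function(c, statistic, feature) {
  if (!statistic %in% names(c@local_results)) {
    stop(sprintf("no local results for statistic '%s' (available: %s)",
                 statistic,
                 if (length(c@local_results))
                   paste(names(c@local_results), collapse = ", ")
                 else "<none>"))
  }
  entry <- c@local_results[[statistic]]
  if (!feature %in% names(entry)) {
    stop(sprintf("statistic '%s' has no results for feature '%s' (features: %s)",
                 statistic, feature, paste(names(entry), collapse = ", ")))
  }
  entry[[feature]]
}

#' Bounding box of a layer or container
#'
#' For a container: smallest axis-aligned rectangle containing every
#' coordinate of every geometry layer and every image extent.
#'
#' @param x a [GeometryLayer-class] or [SpatialFeatureContainer-class].
#' @return a [SpatialExtent-class].
#' @export
setGeneric("bbox", function(x) standardGeneric("bbox"))

#' @rdname bbox
#' @export
setMethod("bbox", "GeometryLayer", function(x) {
  if (n_geometries(x) == 0L) stop("empty geometry layer has no bounding box")
  co <- do.call(rbind, lapply(x@geoms, geom_coords, type = x@geom_type))
  if (is.null(co) || nrow(co) == 0L) stop("layer has no coordinates")
  spatial_extent(min(co[, 1L]), min(co[, 2L]), max(co[, 1L]), max(co[, 2L]))
})

#' @rdname bbox
#' @export
setMethod("bbox", "SpatialFeatureContainer", function(x) {
  boxes <- list()
  for (axis in c("col", "row", "annot")) {
    for (ly in slot(x, geom_slot(axis))) {
      if (n_geometries(ly) > 0L) {
        co <- do.call(rbind, lapply(ly@geoms, geom_coords, type = ly@geom_type))
        if (!is.null(co) && nrow(co) > 0L) {
          boxes[[length(boxes) + 1L]] <-
            c(min(co[, 1L]), min(co[, 2L]), max(co[, 1L]), max(co[, 2L]))
        }
      }
    }
  }
  for (img in x@images) boxes[[length(boxes) + 1L]] <- as_extent_vec(img@extent)
  if (length(boxes) == 0L) {
    stop("container has no geometry layers or images; bounding box undefined")
  }
  b <- do.call(rbind, boxes)
  spatial_extent(min(b[, 1L]), min(b[, 2L]), max(b[, 3L]), max(b[, 4L]))
})

## ---- synchronized subsetting ----

check_idx <- function(idx, n, what) {
  if (is.logical(idx)) {
    if (length(idx) != n) stop(what, " logical index has wrong length")
    idx <- which(idx)
  }
  idx <- as.integer(idx)
  if (length(idx) && (min(idx) < 1L || max(idx) > n)) {
    stop(sprintf("%s index out of range [1, %d]", what, n))
  }
  if (anyDuplicated(idx)) {
    stop(what, " indices must be duplicate-free (replication is not supported)")
  }
  idx
}

subset_layer <- function(layer, idx) {
  geometry_layer(layer@geoms[idx], layer@geom_type,
                 layer@attrs[idx, , drop = FALSE])
}

#' Subset a container with synchronized bookkeeping
#'
#' Filters assays, metadata, col/row geometry layers, and local-results rows
#' consistently. Graphs on a filtered axis keep only surviving nodes and the
#' edges between them and are flagged `subsetted = TRUE` in their
#' `method_meta`; row-standardized weights are re-normalized over the
#' surviving neighbors. Annotation geometries and images pass through
#' unchanged. Indices must be in range and duplicate-free.
#'
#' @param c a [SpatialFeatureContainer-class].
#' @param row_idx integer or logical selection of features (default all).
#' @param col_idx integer or logical selection of locations (default all).
#' @return the subsetted container.
#' @export
subset_container <- function(c, row_idx = seq_len(n_features(c)),
                             col_idx = seq_len(n_locations(c))) {
  row_idx <- check_idx(row_idx, n_features(c), "row")
  col_idx <- check_idx(col_idx, n_locations(c), "column")
  c@assays <- lapply(c@assays, function(a) a[row_idx, col_idx, drop = FALSE])
  c@row_meta <- c@row_meta[row_idx, , drop = FALSE]
  c@col_meta <- c@col_meta[col_idx, , drop = FALSE]
  c@col_geometries <- lapply(c@col_geometries, subset_layer, idx = col_idx)
  c@row_geometries <- lapply(c@row_geometries, subset_layer, idx = row_idx)
  c@local_results <- lapply(c@local_results, function(entry)
    lapply(entry, function(m) m[col_idx, , drop = FALSE]))
  c@col_graphs <- lapply(c@col_graphs, subset_graph, idx = col_idx)
  validObject(c)
  c
}

#' @rdname subset_container
#' @param x a [SpatialFeatureContainer-class].
#' @param i,j feature and location selections.
#' @param ... ignored.
#' @param drop ignored (never drops).
#' @export
setMethod("[", c("SpatialFeatureContainer", "ANY", "ANY", "ANY"),
  function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(n_features(x))
    if (missing(j)) j <- seq_len(n_locations(x))
    subset_container(x, i, j)
  })

#' @export
setMethod("show", "SpatialFeatureContainer", function(object) {
  cat(sprintf("SpatialFeatureContainer: %d features x %d locations [%s]\n",
              n_features(object), n_locations(object), object@units))
  cat("  assays:", paste(names(object@assays), collapse = ", "), "\n")
  for (axis in c("col", "row", "annot")) {
    nms <- geometry_names(object, axis)
    if (length(nms)) cat(sprintf("  %s geometries: %s\n", axis,
                                 paste(nms, collapse = ", ")))
  }
  if (length(object@col_graphs))
    cat("  col graphs:", paste(names(object@col_graphs), collapse = ", "), "\n")
  if (length(object@annot_graphs))
    cat("  annot graphs:", paste(names(object@annot_graphs), collapse = ", "), "\n")
  if (length(object@local_results))
    cat("  local results:", paste(names(object@local_results), collapse = ", "), "\n")
  if (length(object@images))
    cat("  images:", paste(names(object@images), collapse = ", "), "\n")
})
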