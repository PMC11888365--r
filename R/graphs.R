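#' Spatial neighborhood graphs
#'
#' Four constructors share one output type, [SpatialGraph-class]: k nearest
#' neighbors, distance bands, Delaunay triangulation (optionally pruned to
#' the Gabriel graph), and queen polygon contiguity. All produce symmetric
#' relations with binary weights; [row_standardize()] converts to
#' row-standardized style where each node's outgoing weights sum to 1.
#' Edge distances (where meaningful) are recorded in `method_meta$distances`,
#' not as weights.
#'
#' @name spatial-graphs
NULL

layer_points <- function(layer) {
  if (layer@geom_type == "POINT") {
    return(do.call(rbind, layer@geoms))
  }
  stop("a POINT geometry layer is required (got ", layer@geom_type, ")")
}

edges_df <- function(i, j, weight = 1) {
  ## store each unordered pair once, i < j, sorted
  lo <- pmin(i, j); hi <- pmax(i, j)
  keep <- !duplicated(paste(lo, hi)) & lo != hi
  lo <- lo[keep]; hi <- hi[keep]
  o <- order(lo, hi)
  data.frame(i = as.integer(lo[o]), j = as.integer(hi[o]),
             weight = rep(as.numeric(weight), length.out = sum(keep))[o])
}

#' k-nearest-neighbor graph
#'
#' Each point is linked to its `k` nearest neighbors (Euclidean distance,
#' exact ties broken toward the lower index); the directed neighbor sets are
#' then symmetrized, by default with the union rule (an edge exists if either
#' point is among the other's `k` nearest).
#'
#' @param points a POINT [GeometryLayer-class].
#' @param k number of neighbors, `1 <= k < n`.
#' @param sym `"union"` (default) or `"mutual"` (intersection).
#' @return a binary [SpatialGraph-class].
#' @export
graph_knn <- function(points, k, sym = c("union", "mutual")) {
  sym <- match.arg(sym)
  pts <- layer_points(points)
  n <- nrow(pts)
  if (k < 1L) stop("k must be >= 1")
  if (k >= n) stop(sprintf("k = %d must be smaller than the number of points (%d)", k, n))
  d <- as.matrix(stats::dist(pts))
  nb <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    o <- order(d[i, -i], seq_len(n)[-i])  # ties -> lower index
    nb[i, ] <- (seq_len(n)[-i])[o][seq_len(k)]
  }
  ii <- rep(seq_len(n), each = k)
  jj <- as.integer(t(nb))
  if (sym == "union") {
    e <- edges_df(ii, jj)
  } else {
    key <- paste(pmin(ii, jj), pmax(ii, jj))
    mutual <- key[duplicated(key)]
    keep <- key %in% mutual & ii < jj
    e <- edges_df(ii[keep], jj[keep])
  }
  dists <- d[cbind(e$i, e$j)]
  spatial_graph(n, e, method_meta = list(method = "knn",
                                         params = list(k = k, sym = sym),
                                         distances = dists))
}

#' Distance-band graph
#'
#' Edge between two points iff their Euclidean distance is `<= d_max`
#' (inclusive). Isolated nodes are allowed.
#'
#' @inheritParams graph_knn
#' @param d_max distance threshold, `> 0`.
#' @export
graph_distance <- function(points, d_max) {
  if (d_max <= 0) stop("d_max must be > 0")
  pts <- layer_points(points)
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  idx <- which(upper.tri(d) & d <= d_max, arr.ind = TRUE)
  e <- edges_df(idx[, 1L], idx[, 2L])
  spatial_graph(n, e, method_meta = list(method = "distance",
                                         params = list(d_max = d_max),
                                         distances = d[cbind(e$i, e$j)]))
}

#' Delaunay triangulation graph, optionally Gabriel-pruned
#'
#' Edges of the Delaunay triangulation of the points. With
#' `prune = "gabriel"` an edge (i, j) is kept only if the open disk whose
#' diameter is the segment ij contains no other point (the Gabriel graph,
#' always a subgraph of the Delaunay triangulation).
#'
#' @inheritParams graph_knn
#' @param prune `"none"` or `"gabriel"`.
#' @export
graph_delaunay <- function(points, prune = c("none", "gabriel")) {
  prune <- match.arg(prune)
  pts <- layer_points(points)
  n <- nrow(pts)
  if (n < 3L) stop("Delaunay triangulation needs at least 3 points")
  ctr <- pts - matrix(colMeans(pts), n, 2L, byrow = TRUE)
  if (qr(ctr)$rank < 2L) {
    stop("all points are collinear; the Delaunay triangulation is undefined")
  }
  dd <- deldir::deldir(pts[, 1L], pts[, 2L], suppressMsge = TRUE)
  e <- edges_df(dd$delsgs$ind1, dd$delsgs$ind2)
  if (prune == "gabriel") {
    keep <- vapply(seq_len(nrow(e)), function(r) {
      gabriel_keep(pts, e$i[r], e$j[r])
    }, TRUE)
    e <- e[keep, , drop = FALSE]
  }
  d <- sqrt(rowSums((pts[e$i, , drop = FALSE] - pts[e$j, , drop = FALSE])^2))
  spatial_graph(n, e, method_meta = list(method = "delaunay",
                                         params = list(prune = prune),
                                         distances = d))
}

## TRUE when no third point lies strictly inside the disk with diameter ij
gabriel_keep <- function(pts, i, j) {
  m <- (pts[i, ] + pts[j, ]) / 2
  r2 <- sum((pts[i, ] - m)^2)
  d2 <- (pts[, 1L] - m[1L])^2 + (pts[, 2L] - m[2L])^2
  d2[c(i, j)] <- Inf
  all(d2 >= r2)
}

#' Queen contiguity graph for polygons
#'
#' Two polygons are neighbors iff their boundaries share at least one point
#' (edge or corner contact both count), detected within a snap tolerance.
#'
#' @param polygons a POLYGON or MULTIPOLYGON [GeometryLayer-class].
#' @param snap coordinate tolerance for boundary contact (default `1e-9`).
#' @export
graph_contiguity <- function(polygons, snap = 1e-9) {
  if (!is_polygonal(polygons@geom_type)) {
    stop("contiguity requires a POLYGON or MULTIPOLYGON layer")
  }
  n <- n_geometries(polygons)
  segs <- lapply(polygons@geoms, boundary_segments, type = polygons@geom_type)
  boxes <- t(vapply(polygons@geoms, geom_bbox, numeric(4),
                    type = polygons@geom_type))
  ii <- integer(0); jj <- integer(0)
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in seq.int(i + 1L, n)) {
      bi <- boxes[i, ]; bj <- boxes[j, ]
      if (bi[1L] > bj[3L] + snap || bj[1L] > bi[3L] + snap ||
          bi[2L] > bj[4L] + snap || bj[2L] > bi[4L] + snap) next
      if (boundaries_touch(segs[[i]], segs[[j]], snap)) {
        ii <- c(ii, i); jj <- c(jj, j)
      }
    }
  }
  spatial_graph(n, edges_df(ii, jj),
                method_meta = list(method = "contiguity",
                                   params = list(snap = snap)))
}

boundaries_touch <- function(sa, sb, snap) {
  for (p in seq_len(nrow(sa$a))) {
    for (q in seq_len(nrow(sb$a))) {
      if (dist_segments(sa$a[p, ], sa$b[p, ], sb$a[q, ], sb$b[q, ]) <= snap) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Row-standardize a spatial graph
#'
#' Converts binary weights to row-standardized style: the edge list becomes
#' directed, with weight `1/deg(i)` on each edge leaving node `i`, so every
#' non-isolated node's outgoing weights sum to 1.
#'
#' @param g a [SpatialGraph-class].
#' @export
row_standardize <- function(g) {
  if (g@style == "row_standardized") return(g)
  e <- g@edges
  di <- c(e$i, e$j); dj <- c(e$j, e$i)
  deg <- tabulate(di, nbins = g@n_nodes)
  w <- 1 / deg[di]
  o <- order(di, dj)
  ed <- data.frame(i = di[o], j = dj[o], weight = w[o])
  new("SpatialGraph", n_nodes = g@n_nodes, edges = ed,
      style = "row_standardized", directed = TRUE,
      method_meta = g@method_meta)
}

#' Adjacency / weights matrix of a graph
#' @param g a [SpatialGraph-class].
#' @return a sparse `Matrix::dgCMatrix`, `n_nodes x n_nodes`.
#' @export
graph_weights <- function(g) {
  e <- g@edges
  if (g@directed) {
    Matrix::sparseMatrix(i = e$i, j = e$j, x = e$weight,
                         dims = c(g@n_nodes, g@n_nodes))
  } else {
    Matrix::sparseMatrix(i = c(e$i, e$j), j = c(e$j, e$i),
                         x = rep(e$weight, 2L),
                         dims = c(g@n_nodes, g@n_nodes))
  }
}

## Restrict a graph to nodes idx (renumbered in order of idx); flags
## subsetted = TRUE, re-normalizes row-standardized weights.
subset_graph <- function(g, idx) {
  idx <- as.integer(idx)
  newid <- rep(NA_integer_, g@n_nodes)
  newid[idx] <- seq_along(idx)
  e <- g@edges
  keep <- !is.na(newid[e$i]) & !is.na(newid[e$j])
  e <- e[keep, , drop = FALSE]
  dist_kept <- NULL
  if (!is.null(g@method_meta$distances) &&
      length(g@method_meta$distances) == length(keep)) {
    dist_kept <- g@method_meta$distances[keep]
  }
  e$i <- newid[e$i]; e$j <- newid[e$j]
  mm <- g@method_meta
  mm$subsetted <- TRUE
  if (!is.null(dist_kept)) mm$distances <- dist_kept
  if (g@style == "row_standardized") {
    deg <- tabulate(e$i, nbins = length(idx))
    e$weight <- 1 / deg[e$i]
    o <- order(e$i, e$j)
    e <- e[o, , drop = FALSE]
  }
  rownames(e) <- NULL
  new("SpatialGraph", n_nodes = length(idx), edges = e, style = g@style,
      directed = g@directed, method_meta = mm)
}

#' Build and store a spatial graph with a uniform interface
#'
#' Dispatches to [graph_knn()], [graph_distance()], [graph_delaunay()], or
#' [graph_contiguity()] on the named layer, optionally row-standardizes, and
#' stores the result (with full method metadata, including the source layer
#' name) under `col_graphs` or `annot_graphs`. Re-running with the same
#' `graph_name` overwrites.
#'
#' @param c a [SpatialFeatureContainer-class].
#' @param scope `"col"` or `"annot"`.
#' @param layer geometry layer name within that scope.
#' @param method `"knn"`, `"distance"`, `"delaunay"`, or `"contiguity"`.
#' @param params list of method parameters (`k`, `d_max`, `prune`, `snap`,
#'   `sym`).
#' @param graph_name name to store the graph under (default: the method).
#' @param style `"binary"` or `"row_standardized"`.
#' @return the updated container.
#' @export
find_spatial_graph <- function(c, scope = c("col", "annot"), layer,
                               method = c("knn", "distance", "delaunay",
                                          "contiguity"),
                               params = list(), graph_name = method,
                               style = c("binary", "row_standardized")) {
  scope <- match.arg(scope)
  method <- match.arg(method)
  style <- match.arg(style)
  axis <- if (scope == "col") "col" else "annot"
  ly <- get_geometry(c, axis, layer)
  g <- switch(method,
    knn = do.call(graph_knn, c(list(points = ly), params)),
    distance = do.call(graph_distance, c(list(points = ly), params)),
    delaunay = do.call(graph_delaunay, c(list(points = ly), params)),
    contiguity = do.call(graph_contiguity, c(list(polygons = ly), params))
  )
  g@method_meta$layer <- layer
  if (style == "row_standardized") g <- row_standardize(g)
  set_graph(c, scope, graph_name, g)
}
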