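#' Build a regular grid of bin polygons over an extent
#'
#' Square grids are axis-aligned, anchored at `origin` (default the extent's
#' lower-left corner), with `ceiling` many cells per axis so the extent is
#' covered completely (cells may overhang the boundary). Hexagonal grids use
#' flat-topped hexagons with center-to-center horizontal spacing equal to
#' `cellsize` (circumradius `2 * cellsize / 3`), odd columns offset
#' vertically by half the vertical pitch; enough rows/columns are generated
#' to cover the extent. Cells are pairwise interior-disjoint by construction.
#'
#' @param extent a [SpatialExtent-class] or numeric `c(xmin, ymin, xmax,
#'   ymax)`.
#' @param kind `"square"` or `"hex"`.
#' @param cellsize square side length, or hex center-to-center horizontal
#'   spacing (`> 0`).
#' @param origin numeric `c(x, y)` grid anchor (default extent lower-left).
#' @return a POLYGON [GeometryLayer-class] with attribute columns `grid_id`,
#'   `grid_row`, `grid_col`.
#' @export
make_grid <- function(extent, kind = c("square", "hex"), cellsize,
                      origin = NULL) {
  kind <- match.arg(kind)
  if (cellsize <= 0) stop("cellsize must be > 0")
  e <- as_extent_vec(extent)
  if (is.null(origin)) origin <- c(e[1], e[2])
  if (kind == "square") {
    ncx <- max(1L, as.integer(ceiling((e[3] - origin[1]) / cellsize)))
    ncy <- max(1L, as.integer(ceiling((e[4] - origin[2]) / cellsize)))
    geoms <- vector("list", ncx * ncy)
    gr <- integer(ncx * ncy); gc <- integer(ncx * ncy)
    k <- 0L
    for (iy in seq_len(ncy)) {
      for (ix in seq_len(ncx)) {
        k <- k + 1L
        x0 <- origin[1] + (ix - 1L) * cellsize
        y0 <- origin[2] + (iy - 1L) * cellsize
        geoms[[k]] <- gf_rect(c(x0, y0, x0 + cellsize, y0 + cellsize))
        gr[k] <- iy; gc[k] <- ix
      }
    }
  } else {
    R <- 2 * cellsize / 3           # circumradius; horizontal pitch = 1.5 R
    vp <- sqrt(3) * R               # vertical pitch
    ncx <- as.integer(ceiling((e[3] - origin[1]) / cellsize)) + 2L
    ncy <- as.integer(ceiling((e[4] - origin[2]) / vp)) + 2L
    ang <- pi / 3 * (0:5)           # flat-topped: vertices at 0, 60, ... deg
    hx <- R * cos(ang); hy <- R * sin(ang)
    geoms <- list(); gr <- integer(0); gc <- integer(0)
    for (ix in seq_len(ncx) - 1L) {
      cx <- origin[1] + ix * cellsize
      yoff <- if (ix %% 2L == 1L) vp / 2 else 0
      for (iy in seq_len(ncy) - 1L) {
        cy <- origin[2] + iy * vp + yoff
        ## keep only cells that can touch the extent
        if (cx + R < e[1] || cx - R > e[3] ||
            cy + vp / 2 < e[2] || cy - vp / 2 > e[4]) next
        v <- cbind(cx + hx, cy + hy)
        geoms[[length(geoms) + 1L]] <- gf_polygon(rbind(v, v[1L, ]))
        gr <- c(gr, iy + 1L); gc <- c(gc, ix + 1L)
      }
    }
    ## cover the lower margin: one extra row below the origin
    for (ix in seq_len(ncx) - 1L) {
      cx <- origin[1] + ix * cellsize
      yoff <- if (ix %% 2L == 1L) vp / 2 else 0
      cy <- origin[2] - vp + yoff
      if (cx + R < e[1] || cx - R > e[3] || cy + vp / 2 < e[2]) next
      v <- cbind(cx + hx, cy + hy)
      geoms[[length(geoms) + 1L]] <- gf_polygon(rbind(v, v[1L, ]))
      gr <- c(gr, 0L); gc <- c(gc, ix + 1L)
    }
  }
  geometry_layer(geoms, "POLYGON",
                 data.frame(grid_id = seq_along(geoms), grid_row = gr,
                            grid_col = gc))
}

## Assign each point to at most one polygon: iterate polygons in order, so a
## point on a shared boundary goes to the LOWEST polygon index. Returns an
## integer vector (NA = outside all polygons).
assign_points_to_polygons <- function(pts, polygons) {
  pts <- matrix(pts, ncol = 2L)
  n <- nrow(pts)
  assign <- rep(NA_integer_, n)
  boxes <- t(vapply(polygons@geoms, geom_bbox, numeric(4),
                    type = polygons@geom_type))
  for (p in seq_len(n_geometries(polygons))) {
    open <- which(is.na(assign))
    if (length(open) == 0L) break
    b <- boxes[p, ]
    cand <- open[pts[open, 1L] >= b[1L] & pts[open, 1L] <= b[3L] &
                 pts[open, 2L] >= b[2L] & pts[open, 2L] <= b[4L]]
    if (length(cand) == 0L) next
    hit <- points_in_polygeom(pts[cand, , drop = FALSE],
                              polygons@geoms[[p]], polygons@geom_type) > 0L
    assign[cand[hit]] <- p
  }
  assign
}

#' Aggregate cell-level data into bins
#'
#' Each location (cell/spot) is assigned to at most one bin polygon by its
#' assignment point — the col geometry itself when it is a POINT layer, the
#' polygon centroid otherwise; a point on a shared bin boundary goes to the
#' lowest bin index. For every feature and bin, `fun` is applied to the
#' feature's assay values over the cells in that bin (any function mapping a
#' numeric vector to a scalar; `sum` over empty bins gives 0, other functions
#' give `NA`). Cells falling outside all bins are dropped and their number
#' reported via a message and in the result's `metadata$n_dropped`.
#'
#' @param c a [SpatialFeatureContainer-class] with at least one col geometry.
#' @param by a POLYGON [GeometryLayer-class] of bins (e.g. from
#'   [make_grid()]).
#' @param fun summary function or its name (default `sum`).
#' @param assay assay to aggregate (default `"counts"`).
#' @param colgeom col geometry layer giving the assignment points (default:
#'   `"centroids"` if present, else the first col layer).
#' @return a new container with one column per bin; `by` becomes its col
#'   geometry `"bins"`; provenance is recorded in `metadata$aggregation`.
#' @export
aggregate_cells <- function(c, by, fun = sum, assay = "counts",
                            colgeom = NULL) {
  if (length(c@col_geometries) == 0L) {
    stop("aggregate_cells needs a col geometry layer for assignment points")
  }
  if (is.null(colgeom)) {
    colgeom <- if ("centroids" %in% geometry_names(c, "col")) "centroids"
               else geometry_names(c, "col")[1L]
  }
  fun_name <- if (is.character(fun)) fun else deparse(substitute(fun))[1L]
  fun <- match.fun(fun)
  ly <- get_geometry(c, "col", colgeom)
  pts <- if (ly@geom_type == "POINT") do.call(rbind, ly@geoms)
         else t(vapply(ly@geoms, geom_centroid, numeric(2),
                       type = ly@geom_type))
  assign <- assign_points_to_polygons(pts, by)
  n_drop <- sum(is.na(assign))
  if (n_drop > 0L) {
    message(n_drop, " location(s) outside all bins were dropped")
  }
  a <- get_assay(c, assay)
  nb <- n_geometries(by)
  out <- matrix(NA_real_, nrow(a), nb)
  is_sum <- identical(fun, sum)
  for (b in seq_len(nb)) {
    cells <- which(!is.na(assign) & assign == b)
    if (length(cells) == 0L) {
      if (is_sum) out[, b] <- 0
      next
    }
    out[, b] <- apply(a[, cells, drop = FALSE], 1L, fun)
  }
  dimnames(out) <- list(rownames(a), paste0("bin_", seq_len(nb)))
  res <- new_container(pmax(out, 0),
                       data.frame(bin = paste0("bin_", seq_len(nb)),
                                  by@attrs,
                                  check.names = FALSE),
                       c@row_meta, units = c@units)
  ## arbitrary summary functions may produce negatives; store under
  ## "aggregated" in that case so the counts invariant stays meaningful
  if (isTRUE(any(out < 0, na.rm = TRUE))) {
    res@assays <- list(aggregated = out)
  } else {
    res@assays <- list(counts = out)
  }
  res <- set_geometry(res, "col", "bins", by)
  res@metadata$aggregation <- list(source_assay = assay, fun = fun_name,
                                   colgeom = colgeom, n_dropped = n_drop)
  res@metadata$n_dropped <- n_drop
  validObject(res)
  res
}

#' Count labeled points into polygons
#'
#' Entry (g, p) is the number of points labeled `g` lying inside or on the
#' boundary of polygon `p`; a point on a shared boundary is counted once, in
#' the lowest polygon index. Points outside all polygons contribute nowhere.
#'
#' @param points a POINT or MULTIPOINT [GeometryLayer-class] whose attribute
#'   table carries the label column (for MULTIPOINT, one label per geometry).
#' @param polygons a POLYGON [GeometryLayer-class].
#' @param label_col name of the label column (default the first attribute
#'   column).
#' @return a sparse `Matrix::dgCMatrix`, labels x polygons.
#' @export
count_points_in_polygons <- function(points, polygons, label_col = NULL) {
  if (is.null(label_col)) {
    if (ncol(points@attrs) == 0L) stop("points layer has no label column")
    label_col <- names(points@attrs)[1L]
  }
  if (!label_col %in% names(points@attrs)) {
    stop("no label column '", label_col, "' in the points layer")
  }
  per_geom_labels <- as.character(points@attrs[[label_col]])
  if (points@geom_type == "POINT") {
    pts <- do.call(rbind, points@geoms)
    labels <- per_geom_labels
  } else if (points@geom_type == "MULTIPOINT") {
    npts <- vapply(points@geoms, nrow, 0L)
    pts <- do.call(rbind, points@geoms)
    labels <- rep(per_geom_labels, npts)
  } else {
    stop("points layer must be POINT or MULTIPOINT")
  }
  ulab <- unique(per_geom_labels)
  np <- n_geometries(polygons)
  if (is.null(pts) || nrow(pts) == 0L) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(length(ulab), np),
                                dimnames = list(ulab, NULL)))
  }
  assign <- assign_points_to_polygons(pts, polygons)
  ok <- !is.na(assign)
  Matrix::sparseMatrix(i = match(labels[ok], ulab), j = assign[ok],
                       x = rep(1, sum(ok)), dims = c(length(ulab), np),
                       dimnames = list(ulab, NULL))
}

#' Aggregate per-gene transcript spots into a new count matrix
#'
#' Uses the container's row geometry of per-gene transcript multipoints:
#' every spot is binned into at most one polygon of `by` (boundary ties to
#' the lowest bin index), and the resulting counts form the assay of a new
#' container whose rows stay aligned to the input features (genes without
#' spots give all-zero rows) and whose columns are the bin polygons.
#'
#' @param c a [SpatialFeatureContainer-class] with a MULTIPOINT row geometry.
#' @param by a POLYGON [GeometryLayer-class] of bins.
#' @param rowgeom row geometry layer name (default the first row layer).
#' @return a new container, `n_features(c) x n_geometries(by)`.
#' @export
aggregate_transcripts <- function(c, by, rowgeom = NULL) {
  if (length(c@row_geometries) == 0L) {
    stop("aggregate_transcripts needs a row geometry of transcript spots")
  }
  if (is.null(rowgeom)) rowgeom <- geometry_names(c, "row")[1L]
  ly <- get_geometry(c, "row", rowgeom)
  if (ly@geom_type != "MULTIPOINT") {
    stop("row geometry '", rowgeom, "' must be MULTIPOINT transcript spots")
  }
  npts <- vapply(ly@geoms, nrow, 0L)
  nb <- n_geometries(by)
  counts <- matrix(0, n_features(c), nb)
  if (sum(npts) > 0L) {
    pts <- do.call(rbind, ly@geoms)
    gene_idx <- rep(seq_along(ly@geoms), npts)
    assign <- assign_points_to_polygons(pts, by)
    ok <- !is.na(assign)
    if (any(ok)) {
      tab <- table(factor(gene_idx[ok], levels = seq_len(n_features(c))),
                   factor(assign[ok], levels = seq_len(nb)))
      counts <- matrix(as.numeric(tab), n_features(c), nb)
    }
  }
  dimnames(counts) <- list(rownames(get_assay(c)), paste0("bin_", seq_len(nb)))
  res <- new_container(counts,
                       data.frame(bin = paste0("bin_", seq_len(nb)),
                                  by@attrs, check.names = FALSE),
                       c@row_meta, units = c@units)
  res <- set_geometry(res, "col", "bins", by)
  res@metadata$aggregation <- list(source = "transcript_spots",
                                   rowgeom = rowgeom)
  res
}
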