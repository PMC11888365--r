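#' Crop a container with a bounding box or region geometry
#'
#' Locations (matrix columns) are kept iff the chosen predicate holds between
#' their geometry in layer `colgeom` and the query (`contains_in` keeps
#' columns whose geometry lies within the query). Annotation layers are
#' either clipped by geometric intersection with the query
#' (`annot_op = "clip"`, convex queries only) or kept whole iff intersecting
#' (`"keep_whole"`); emptied annotation geometries are dropped. Images are
#' cropped to the intersection of the query bounding box with their extent
#' (dropped if disjoint). Column filtering then follows the
#' [subset_container()] contract. A query disjoint from everything yields a
#' valid container with zero locations.
#'
#' @param c a [SpatialFeatureContainer-class].
#' @param query a [SpatialExtent-class], numeric `c(xmin, ymin, xmax, ymax)`,
#'   or a POLYGON geometry structure.
#' @param colgeom name of the col geometry layer used for the predicate.
#' @param predicate `"intersects"`, `"contains_in"`, or `"covered_by"`.
#' @param annot_op `"clip"` or `"keep_whole"`.
#' @return the cropped container.
#' @export
crop <- function(c, query, colgeom,
                 predicate = c("intersects", "contains_in", "covered_by"),
                 annot_op = c("clip", "keep_whole")) {
  predicate <- match.arg(predicate)
  annot_op <- match.arg(annot_op)
  qpoly <- as_query_polygon(query)
  ly <- get_geometry(c, "col", colgeom)
  keep <- vapply(ly@geoms, function(g) {
    switch(predicate,
      intersects  = geom_predicate(g, ly@geom_type, qpoly, "POLYGON",
                                   "intersects"),
      contains_in = geom_predicate(g, ly@geom_type, qpoly, "POLYGON",
                                   "within"),
      covered_by  = pred_covered_by(g, ly@geom_type, qpoly, "POLYGON"))
  }, TRUE)
  ## annotation layers
  new_annot <- list()
  for (nm in names(c@annot_geometries)) {
    al <- c@annot_geometries[[nm]]
    if (annot_op == "keep_whole") {
      ak <- vapply(al@geoms, function(g)
        geom_predicate(g, al@geom_type, qpoly, "POLYGON", "intersects"), TRUE)
      if (any(ak)) new_annot[[nm]] <- subset_layer(al, which(ak))
    } else {
      clipped <- lapply(al@geoms, clip_geom_convex, type = al@geom_type,
                        clip_poly = qpoly)
      ok <- !vapply(clipped, is.null, TRUE)
      if (any(ok)) {
        types <- unique(vapply(clipped[ok], `[[`, "", "type"))
        ## clipping a POLYGON layer can only return POLYGONs etc.
        new_annot[[nm]] <- geometry_layer(
          lapply(clipped[ok], `[[`, "geom"), types[[1L]],
          al@attrs[ok, , drop = FALSE])
      }
    }
  }
  c@annot_geometries <- new_annot
  ## images: crop to bbox(query) intersected with each image extent
  qb <- geom_bbox(qpoly, "POLYGON")
  new_imgs <- list()
  for (nm in names(c@images)) {
    img <- c@images[[nm]]
    e <- as_extent_vec(img_extent(img))
    if (qb[1] < e[3] && qb[3] > e[1] && qb[2] < e[4] && qb[4] > e[2]) {
      new_imgs[[nm]] <- crop_image(img, qb)
    }
  }
  c@images <- new_imgs
  subset_container(c, col_idx = which(keep))
}

as_query_polygon <- function(query) {
  if (is(query, "SpatialExtent") ||
      (is.numeric(query) && length(query) == 4L && is.null(dim(query)))) {
    return(gf_rect(query))
  }
  if (is.list(query) && is.matrix(query[[1L]])) return(query)  # POLYGON
  if (is.matrix(query)) return(gf_polygon(query))
  stop("query must be an extent or a POLYGON geometry")
}

#' Relate two geometry layers with a spatial predicate
#'
#' Evaluates the predicate for every pair (i, j), by exhaustive pairwise
#' testing with a bounding-box prefilter.
#'
#' @param a,b [GeometryLayer-class] objects (non-empty).
#' @param predicate `"intersects"`, `"contains"`, `"within"`, or `"touches"`.
#' @return a sparse logical `Matrix::lgCMatrix`, `n_geometries(a) x
#'   n_geometries(b)`; entry (i, j) is `TRUE` iff `predicate(a_i, b_j)`.
#' @export
relate <- function(a, b, predicate = c("intersects", "contains", "within",
                                       "touches")) {
  predicate <- match.arg(predicate)
  if (n_geometries(a) == 0L || n_geometries(b) == 0L) {
    stop("relate requires two non-empty layers")
  }
  ii <- integer(0); jj <- integer(0)
  for (i in seq_len(n_geometries(a))) {
    for (j in seq_len(n_geometries(b))) {
      if (geom_predicate(a@geoms[[i]], a@geom_type,
                         b@geoms[[j]], b@geom_type, predicate)) {
        ii <- c(ii, i); jj <- c(jj, j)
      }
    }
  }
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = TRUE,
                            dims = c(n_geometries(a), n_geometries(b)))
  methods::as(m, "lMatrix")
}

#' Per-location summary of intersecting annotation attributes
#'
#' For each column geometry, applies `fun` over the chosen attribute of the
#' annotation geometries that intersect it (e.g. mean myofiber area per
#' spot). Columns intersecting no annotation geometry get `NA`
#' (`fun = "count"` gives 0).
#'
#' @param c a [SpatialFeatureContainer-class].
#' @param annot annotation layer name.
#' @param colgeom col geometry layer name.
#' @param attribute attribute column in the annotation layer (ignored for
#'   `count`).
#' @param fun `"mean"`, `"sum"`, `"count"`, `"min"`, or `"max"`.
#' @return numeric vector of length `n_locations(c)`.
#' @export
annot_summary <- function(c, annot, colgeom, attribute = NULL,
                          fun = c("mean", "sum", "count", "min", "max")) {
  fun <- match.arg(fun)
  al <- get_geometry(c, "annot", annot)
  cl <- get_geometry(c, "col", colgeom)
  if (fun != "count") {
    if (is.null(attribute) || !attribute %in% names(al@attrs)) {
      stop("unknown attribute '", attribute %||% "<missing>",
           "' in annot layer '", annot, "' (columns: ",
           paste(names(al@attrs), collapse = ", "), ")")
    }
    vals <- al@attrs[[attribute]]
  }
  rel <- relate(cl, al, "intersects")
  out <- numeric(n_geometries(cl))
  for (i in seq_len(n_geometries(cl))) {
    hit <- which(rel[i, ])
    out[i] <- if (fun == "count") length(hit)
              else if (length(hit) == 0L) NA_real_
              else match.fun(fun)(vals[hit])
  }
  out
}

#' Split a container by annotation regions
#'
#' Produces one container per geometry of the annotation layer, keeping the
#' columns whose geometry satisfies the predicate with that region. A column
#' matching several regions appears in each of them (regions are treated
#' independently, not as an exclusive partition).
#'
#' @param c a [SpatialFeatureContainer-class].
#' @param annot annotation layer name (each geometry needs a name/id
#'   attribute, or names fall back to the row index).
#' @param colgeom col geometry layer name.
#' @param predicate passed to [geom_predicate()] as
#'   `predicate(col geometry, region)`.
#' @param name_col attribute column holding region names (default: first of
#'   `"name"`, `"id"` present).
#' @return named list of containers.
#' @export
split_by_annotation <- function(c, annot, colgeom, predicate = "intersects",
                                name_col = NULL) {
  al <- get_geometry(c, "annot", annot)
  cl <- get_geometry(c, "col", colgeom)
  if (n_geometries(al) < 1L) stop("annotation layer is empty")
  if (is.null(name_col)) {
    name_col <- intersect(c("name", "id"), names(al@attrs))[1L]
  }
  nms <- if (!is.na(name_col) && !is.null(name_col) && name_col %in% names(al@attrs)) {
    as.character(al@attrs[[name_col]])
  } else {
    as.character(seq_len(n_geometries(al)))
  }
  out <- vector("list", n_geometries(al))
  names(out) <- nms
  for (r in seq_len(n_geometries(al))) {
    keep <- vapply(cl@geoms, function(g)
      geom_predicate(g, cl@geom_type, al@geoms[[r]], al@geom_type, predicate),
      TRUE)
    out[[r]] <- subset_container(c, col_idx = which(keep))
  }
  out
}
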