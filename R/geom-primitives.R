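#' Simple-features geometry primitives
#'
#' Geometries are stored as plain R structures, one convention per type:
#' \describe{
#'   \item{POINT}{numeric vector of length 2, `c(x, y)`.}
#'   \item{MULTIPOINT}{numeric matrix with 2 columns, one point per row
#'     (0 rows is the empty multipoint).}
#'   \item{LINESTRING}{numeric matrix with 2 columns and at least 2 rows.}
#'   \item{POLYGON}{list of rings; each ring is a closed numeric matrix
#'     (first row equals last row) with at least 4 rows. The first ring is
#'     the exterior, any further rings are holes.}
#'   \item{MULTIPOLYGON}{list of POLYGON structures.}
#' }
#' All coordinates are finite doubles in one Cartesian frame (x rightward,
#' y upward).
#'
#' @param x,y coordinates.
#' @name geometry-primitives
NULL

GEOM_TYPES <- c("POINT", "MULTIPOINT", "LINESTRING", "POLYGON", "MULTIPOLYGON")

#' @rdname geometry-primitives
#' @export
gf_point <- function(x, y) c(as.numeric(x), as.numeric(y))

#' @rdname geometry-primitives
#' @param coords numeric matrix with 2 columns.
#' @export
gf_multipoint <- function(coords) {
  coords <- as_coord_matrix(coords, allow_empty = TRUE)
  coords
}

#' @rdname geometry-primitives
#' @export
gf_linestring <- function(coords) {
  coords <- as_coord_matrix(coords)
  if (nrow(coords) < 2L) stop("a LINESTRING needs at least 2 vertices")
  coords
}

#' @rdname geometry-primitives
#' @param rings a coordinate matrix (single exterior ring, closed
#'   automatically) or a list of such matrices (exterior first, then holes).
#' @export
gf_polygon <- function(rings) {
  if (is.matrix(rings) || is.data.frame(rings)) rings <- list(rings)
  lapply(rings, function(r) close_ring(as_coord_matrix(r)))
}

#' @rdname geometry-primitives
#' @param polygons list of POLYGON structures (or matrices, closed per ring).
#' @export
gf_multipolygon <- function(polygons) lapply(polygons, gf_polygon_coerce)

gf_polygon_coerce <- function(p) {
  if (is.matrix(p) || is.data.frame(p)) gf_polygon(p) else gf_polygon(p)
}

#' Axis-aligned rectangle polygon
#'
#' @param extent a [SpatialExtent] or numeric `c(xmin, ymin, xmax, ymax)`.
#' @return a POLYGON structure (single closed ring, counter-clockwise).
#' @export
gf_rect <- function(extent) {
  e <- as_extent_vec(extent)
  gf_polygon(rbind(
    c(e[1], e[2]), c(e[3], e[2]), c(e[3], e[4]), c(e[1], e[4]), c(e[1], e[2])
  ))
}

#' Regular polygon approximating a circle
#'
#' @param center numeric `c(x, y)`.
#' @param radius circle radius.
#' @param n number of vertices (default 32).
#' @return a POLYGON structure.
#' @export
gf_regular_polygon <- function(center, radius, n = 32L) {
  ang <- 2 * pi * (seq_len(n) - 1L) / n
  v <- cbind(center[1] + radius * cos(ang), center[2] + radius * sin(ang))
  gf_polygon(rbind(v, v[1L, , drop = FALSE]))
}

as_coord_matrix <- function(x, allow_empty = FALSE) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 2L, byrow = TRUE)
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  if (ncol(x) != 2L) stop("coordinates must have exactly 2 columns (x, y)")
  if (!allow_empty && nrow(x) == 0L) stop("empty coordinate matrix")
  x
}

close_ring <- function(r) {
  if (nrow(r) < 3L) stop("a polygon ring needs at least 3 distinct vertices")
  if (!isTRUE(all.equal(r[1L, ], r[nrow(r), ], tolerance = 0))) {
    r <- rbind(r, r[1L, , drop = FALSE])
  }
  if (nrow(r) < 4L) stop("a closed polygon ring needs at least 4 rows")
  r
}

## All coordinates of a geometry as an n x 2 matrix
geom_coords <- function(geom, type) {
  switch(type,
    POINT = matrix(geom, ncol = 2L),
    MULTIPOINT = ,
    LINESTRING = geom,
    POLYGON = do.call(rbind, geom),
    MULTIPOLYGON = do.call(rbind, lapply(geom, function(p) do.call(rbind, p))),
    stop("unknown geometry type: ", type)
  )
}

## Rebuild a geometry from transformed coordinates, preserving structure
map_geom_coords <- function(geom, type, f) {
  switch(type,
    POINT = as.numeric(f(matrix(geom, ncol = 2L))),
    MULTIPOINT = ,
    LINESTRING = f(geom),
    POLYGON = lapply(geom, f),
    MULTIPOLYGON = lapply(geom, function(p) lapply(p, f)),
    stop("unknown geometry type: ", type)
  )
}

## Signed area of a closed ring (positive when counter-clockwise)
ring_signed_area <- function(r) {
  n <- nrow(r)
  x <- r[, 1L]; y <- r[, 2L]
  sum(x[-n] * y[-1L] - x[-1L] * y[-n]) / 2
}

ring_self_intersects <- function(r) {
  ## proper crossings between non-adjacent edges of one closed ring
  n <- nrow(r) - 1L
  if (n < 4L) return(FALSE)
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    js <- seq.int(i + 2L, jmax)
    for (j in js) {
      if (segments_properly_cross(r[i, ], r[i + 1L, ], r[j, ], r[j + 1L, ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Area of a polygonal geometry
#'
#' Shoelace area of the exterior ring(s) minus hole rings.
#' @param geom a POLYGON or MULTIPOLYGON structure.
#' @param type geometry type string.
#' @return numeric area.
#' @export
geom_area <- function(geom, type) {
  if (type == "POLYGON") {
    a <- abs(ring_signed_area(geom[[1L]]))
    if (length(geom) > 1L) {
      a <- a - sum(vapply(geom[-1L], function(r) abs(ring_signed_area(r)), 0))
    }
    a
  } else if (type == "MULTIPOLYGON") {
    sum(vapply(geom, geom_area, 0, type = "POLYGON"))
  } else {
    stop("geom_area is defined for POLYGON/MULTIPOLYGON only")
  }
}

ring_centroid <- function(r) {
  n <- nrow(r)
  x <- r[, 1L]; y <- r[, 2L]
  cr <- x[-n] * y[-1L] - x[-1L] * y[-n]
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(r[-n, , drop = FALSE]))
  cx <- sum((x[-n] + x[-1L]) * cr) / (6 * a)
  cy <- sum((y[-n] + y[-1L]) * cr) / (6 * a)
  c(cx, cy)
}

#' Centroid of a geometry
#'
#' Area-weighted centroid for polygons (holes subtracted), mean of
#' vertices/points otherwise.
#' @inheritParams geom_area
#' @return numeric `c(x, y)`.
#' @export
geom_centroid <- function(geom, type) {
  if (type == "POINT") return(geom)
  if (type %in% c("MULTIPOINT", "LINESTRING")) return(colMeans(geom))
  if (type == "POLYGON") {
    cs <- t(vapply(geom, ring_centroid, numeric(2)))
    ws <- vapply(geom, function(r) abs(ring_signed_area(r)), 0)
    ws[-1L] <- -ws[-1L]  # holes subtract
    if (length(ws) == 1L) return(cs[1L, ])
    return(as.numeric(colSums(cs * ws) / sum(ws)))
  }
  if (type == "MULTIPOLYGON") {
    cs <- t(vapply(geom, geom_centroid, numeric(2), type = "POLYGON"))
    ws <- vapply(geom, geom_area, 0, type = "POLYGON")
    return(as.numeric(colSums(cs * ws) / sum(ws)))
  }
  stop("unknown geometry type: ", type)
}

validate_geom <- function(geom, type) {
  co <- geom_coords(geom, type)
  if (nrow(co) > 0L && !all(is.finite(co))) {
    return("geometry has non-finite coordinates")
  }
  if (type == "POINT" && length(geom) != 2L) return("POINT must be length-2")
  if (type == "LINESTRING" && nrow(geom) < 2L) {
    return("LINESTRING needs >= 2 vertices")
  }
  if (type %in% c("POLYGON", "MULTIPOLYGON")) {
    polys <- if (type == "POLYGON") list(geom) else geom
    for (p in polys) {
      for (r in p) {
        if (!isTRUE(all.equal(r[1L, ], r[nrow(r), ], tolerance = 0))) {
          return("polygon ring is not closed")
        }
        if (ring_self_intersects(r)) return("polygon ring self-intersects")
      }
    }
  }
  NULL
}
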