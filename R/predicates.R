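## Low-level computational geometry: segment tests, point-in-polygon,
## spatial predicates, and convex clipping. Point-in-polygon delegates to
## sp::point.in.polygon (even-odd with boundary detection); everything else
## is exact arithmetic on coordinates.

## > 0 counter-clockwise, < 0 clockwise, 0 collinear
orient2d <- function(a, b, c) {
  (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
}

point_on_segment <- function(p, a, b, tol = 0) {
  if (abs(orient2d(a, b, p)) > tol * max(1, sum(abs(b - a)))) return(FALSE)
  p[1] >= min(a[1], b[1]) - tol && p[1] <= max(a[1], b[1]) + tol &&
    p[2] >= min(a[2], b[2]) - tol && p[2] <= max(a[2], b[2]) + tol
}

## closed-set intersection of segments [p1,p2] and [p3,p4]
segments_intersect <- function(p1, p2, p3, p4) {
  d1 <- orient2d(p3, p4, p1); d2 <- orient2d(p3, p4, p2)
  d3 <- orient2d(p1, p2, p3); d4 <- orient2d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  (d1 == 0 && point_on_segment(p1, p3, p4)) ||
    (d2 == 0 && point_on_segment(p2, p3, p4)) ||
    (d3 == 0 && point_on_segment(p3, p1, p2)) ||
    (d4 == 0 && point_on_segment(p4, p1, p2))
}

## strict interior crossing (shared endpoints / boundary contact excluded)
segments_properly_cross <- function(p1, p2, p3, p4) {
  d1 <- orient2d(p3, p4, p1); d2 <- orient2d(p3, p4, p2)
  d3 <- orient2d(p1, p2, p3); d4 <- orient2d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

dist_point_segment <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(sum((p - a)^2)))
  t <- max(0, min(1, sum((p - a) * ab) / len2))
  sqrt(sum((p - a - t * ab)^2))
}

dist_segments <- function(p1, p2, p3, p4) {
  if (segments_intersect(p1, p2, p3, p4)) return(0)
  min(dist_point_segment(p1, p3, p4), dist_point_segment(p2, p3, p4),
      dist_point_segment(p3, p1, p2), dist_point_segment(p4, p1, p2))
}

## Point-in-polygon with hole support.
## Returns per point: 0 outside, 1 strictly inside, 2 on boundary.
points_in_polygon <- function(pts, poly) {
  pts <- matrix(pts, ncol = 2L)
  ext <- poly[[1L]]
  code <- sp::point.in.polygon(pts[, 1L], pts[, 2L], ext[, 1L], ext[, 2L])
  res <- ifelse(code == 0L, 0L, ifelse(code == 1L, 1L, 2L))
  if (length(poly) > 1L) {
    for (hole in poly[-1L]) {
      hc <- sp::point.in.polygon(pts[, 1L], pts[, 2L], hole[, 1L], hole[, 2L])
      res[res == 1L & hc == 1L] <- 0L          # strictly inside a hole
      res[res == 1L & hc %in% c(2L, 3L)] <- 2L # on a hole boundary
    }
  }
  res
}

## 0/1/2 of points against POLYGON or MULTIPOLYGON (max over parts)
points_in_polygeom <- function(pts, geom, type) {
  if (type == "POLYGON") return(points_in_polygon(pts, geom))
  out <- rep(0L, nrow(matrix(pts, ncol = 2L)))
  for (p in geom) out <- pmax(out, points_in_polygon(pts, p))
  out
}

## boundary segments of a geometry as list(a = n x 2, b = n x 2)
boundary_segments <- function(geom, type) {
  rings <- switch(type,
    LINESTRING = list(geom),
    POLYGON = geom,
    MULTIPOLYGON = unlist(geom, recursive = FALSE),
    stop("no boundary segments for type ", type)
  )
  a <- do.call(rbind, lapply(rings, function(r) r[-nrow(r), , drop = FALSE]))
  b <- do.call(rbind, lapply(rings, function(r) r[-1L, , drop = FALSE]))
  list(a = a, b = b)
}

any_segments_intersect <- function(sa, sb, proper = FALSE) {
  f <- if (proper) segments_properly_cross else segments_intersect
  for (i in seq_len(nrow(sa$a))) {
    ## bbox prefilter per segment
    xi <- range(sa$a[i, 1L], sa$b[i, 1L]); yi <- range(sa$a[i, 2L], sa$b[i, 2L])
    for (j in seq_len(nrow(sb$a))) {
      if (max(sb$a[j, 1L], sb$b[j, 1L]) < xi[1L] ||
          min(sb$a[j, 1L], sb$b[j, 1L]) > xi[2L] ||
          max(sb$a[j, 2L], sb$b[j, 2L]) < yi[1L] ||
          min(sb$a[j, 2L], sb$b[j, 2L]) > yi[2L]) next
      if (f(sa$a[i, ], sa$b[i, ], sb$a[j, ], sb$b[j, ])) return(TRUE)
    }
  }
  FALSE
}

is_pointlike <- function(type) type %in% c("POINT", "MULTIPOINT")
is_polygonal <- function(type) type %in% c("POLYGON", "MULTIPOLYGON")

geom_points_matrix <- function(geom, type) {
  if (type == "POINT") matrix(geom, ncol = 2L) else geom
}

geom_bbox <- function(geom, type) {
  co <- geom_coords(geom, type)
  c(min(co[, 1L]), min(co[, 2L]), max(co[, 1L]), max(co[, 2L]))
}

bboxes_overlap <- function(ba, bb) {
  !(ba[3L] < bb[1L] || bb[3L] < ba[1L] || ba[4L] < bb[2L] || bb[4L] < ba[2L])
}

#' Spatial predicate between two geometries
#'
#' Standard simple-features semantics: `intersects` is true when the
#' geometries share at least one point (boundary contact counts);
#' `contains(a, b)` requires every point of `b` to lie in the closure of `a`
#' with at least one point in the interior of `a`; `within(a, b)` is
#' `contains(b, a)`; `touches` requires boundary contact with disjoint
#' interiors.
#'
#' @param ga,gb geometry structures (see [geometry-primitives]).
#' @param ta,tb their geometry types.
#' @param predicate one of `"intersects"`, `"contains"`, `"within"`,
#'   `"touches"`.
#' @return logical scalar.
#' @export
geom_predicate <- function(ga, ta, gb, tb,
                           predicate = c("intersects", "contains", "within",
                                         "touches")) {
  predicate <- match.arg(predicate)
  switch(predicate,
    intersects = pred_intersects(ga, ta, gb, tb),
    contains   = pred_contains(ga, ta, gb, tb),
    within     = pred_contains(gb, tb, ga, ta),
    touches    = pred_touches(ga, ta, gb, tb)
  )
}

pred_intersects <- function(ga, ta, gb, tb) {
  if (!bboxes_overlap(geom_bbox(ga, ta), geom_bbox(gb, tb))) return(FALSE)
  if (is_pointlike(ta) && is_pointlike(tb)) {
    pa <- geom_points_matrix(ga, ta); pb <- geom_points_matrix(gb, tb)
    for (i in seq_len(nrow(pa))) {
      if (any(pb[, 1L] == pa[i, 1L] & pb[, 2L] == pa[i, 2L])) return(TRUE)
    }
    return(FALSE)
  }
  if (is_pointlike(ta)) return(pred_intersects(gb, tb, ga, ta))
  if (is_pointlike(tb)) {
    pb <- geom_points_matrix(gb, tb)
    if (is_polygonal(ta)) return(any(points_in_polygeom(pb, ga, ta) > 0L))
    sa <- boundary_segments(ga, ta)  # linestring
    for (i in seq_len(nrow(pb))) {
      for (j in seq_len(nrow(sa$a))) {
        if (point_on_segment(pb[i, ], sa$a[j, ], sa$b[j, ])) return(TRUE)
      }
    }
    return(FALSE)
  }
  ## both are line/polygon: vertex containment or boundary crossing
  if (is_polygonal(tb)) {
    ca <- geom_coords(ga, ta)
    if (any(points_in_polygeom(ca, gb, tb) > 0L)) return(TRUE)
  }
  if (is_polygonal(ta)) {
    cb <- geom_coords(gb, tb)
    if (any(points_in_polygeom(cb, ga, ta) > 0L)) return(TRUE)
  }
  any_segments_intersect(boundary_segments(ga, ta), boundary_segments(gb, tb))
}

pred_contains <- function(ga, ta, gb, tb) {
  if (is_pointlike(ta)) {
    if (!is_pointlike(tb)) return(FALSE)
    pa <- geom_points_matrix(ga, ta); pb <- geom_points_matrix(gb, tb)
    for (i in seq_len(nrow(pb))) {
      if (!any(pa[, 1L] == pb[i, 1L] & pa[, 2L] == pb[i, 2L])) return(FALSE)
    }
    return(nrow(pb) > 0L)
  }
  if (!is_polygonal(ta)) {
    stop("contains/within with a LINESTRING on the containing side is not supported")
  }
  cb <- geom_coords(gb, tb)
  if (nrow(cb) == 0L) return(FALSE)
  codes <- points_in_polygeom(cb, ga, ta)
  if (any(codes == 0L)) return(FALSE)
  if (is_pointlike(tb)) return(any(codes == 1L))
  ## line/polygon inside polygon: no boundary crossing allowed
  if (any_segments_intersect(boundary_segments(gb, tb),
                             boundary_segments(ga, ta), proper = TRUE)) {
    return(FALSE)
  }
  if (any(codes == 1L)) return(TRUE)
  ## all vertices on the boundary: decide by interior probes of b
  probes <- interior_probes(gb, tb)
  any(points_in_polygeom(probes, ga, ta) == 1L)
}

## representative interior-ish points: edge midpoints and centroid
interior_probes <- function(geom, type) {
  s <- boundary_segments(geom, type)
  mids <- (s$a + s$b) / 2
  rbind(mids, matrix(geom_centroid(geom, type), ncol = 2L))
}

## a lies in the CLOSURE of polygonal b (boundary-only containment allowed)
pred_covered_by <- function(ga, ta, gb, tb) {
  if (!is_polygonal(tb)) stop("covered_by requires a polygonal cover")
  ca <- geom_coords(ga, ta)
  if (nrow(ca) == 0L) return(FALSE)
  if (any(points_in_polygeom(ca, gb, tb) == 0L)) return(FALSE)
  if (is_pointlike(ta)) return(TRUE)
  !any_segments_intersect(boundary_segments(ga, ta),
                          boundary_segments(gb, tb), proper = TRUE)
}

pred_touches <- function(ga, ta, gb, tb) {
  if (!pred_intersects(ga, ta, gb, tb)) return(FALSE)
  if (is_pointlike(ta) && is_pointlike(tb)) return(FALSE) # shared point = interior
  if (is_pointlike(ta)) return(pred_touches(gb, tb, ga, ta))
  if (is_pointlike(tb)) {
    if (!is_polygonal(ta)) stop("touches with LINESTRING is not supported")
    codes <- points_in_polygeom(geom_points_matrix(gb, tb), ga, ta)
    return(all(codes != 1L) && any(codes == 2L))
  }
  if (!is_polygonal(ta) || !is_polygonal(tb)) {
    stop("touches with LINESTRING is not supported")
  }
  !polygon_interiors_intersect(ga, ta, gb, tb)
}

polygon_interiors_intersect <- function(ga, ta, gb, tb) {
  if (any(points_in_polygeom(geom_coords(ga, ta), gb, tb) == 1L)) return(TRUE)
  if (any(points_in_polygeom(geom_coords(gb, tb), ga, ta) == 1L)) return(TRUE)
  if (any_segments_intersect(boundary_segments(ga, ta),
                             boundary_segments(gb, tb), proper = TRUE)) {
    return(TRUE)
  }
  ## coincident or nested-without-vertex-contact cases: interior probes
  any(points_in_polygeom(interior_probes(ga, ta), gb, tb) == 1L) ||
    any(points_in_polygeom(interior_probes(gb, tb), ga, ta) == 1L)
}

## ---- convex clipping (Sutherland-Hodgman) ----

is_convex_ring <- function(r) {
  n <- nrow(r) - 1L
  if (n < 3L) return(FALSE)
  sgn <- 0
  for (i in seq_len(n)) {
    a <- r[i, ]; b <- r[i %% n + 1L, ]; c <- r[(i + 1L) %% n + 1L, ]
    o <- orient2d(a, b, c)
    if (o != 0) {
      if (sgn == 0) sgn <- sign(o) else if (sign(o) != sgn) return(FALSE)
    }
  }
  TRUE
}

ensure_ccw <- function(r) if (ring_signed_area(r) < 0) r[rev(seq_len(nrow(r))), , drop = FALSE] else r

## clip one ring against a convex CCW ring; returns closed ring or NULL
clip_ring_convex <- function(subject, clip_ccw) {
  out <- subject[-nrow(subject), , drop = FALSE]
  nc <- nrow(clip_ccw) - 1L
  for (e in seq_len(nc)) {
    a <- clip_ccw[e, ]; b <- clip_ccw[e + 1L, ]
    input <- out
    if (nrow(input) == 0L) return(NULL)
    out <- matrix(numeric(0), ncol = 2L)
    n <- nrow(input)
    side <- (b[1] - a[1]) * (input[, 2L] - a[2]) -
            (b[2] - a[2]) * (input[, 1L] - a[1])
    for (i in seq_len(n)) {
      j <- i %% n + 1L
      p <- input[i, ]; q <- input[j, ]
      pin <- side[i] >= 0; qin <- side[j] >= 0
      if (pin) out <- rbind(out, p)
      if (pin != qin) {
        t <- side[i] / (side[i] - side[j])
        out <- rbind(out, p + t * (q - p))
      }
    }
  }
  if (nrow(out) < 3L) return(NULL)
  out <- out[!duplicated(round(out, 12L)), , drop = FALSE]
  if (nrow(out) < 3L) return(NULL)
  ring <- close_ring(out)
  if (abs(ring_signed_area(ring)) < 1e-12) return(NULL)
  ring
}

## clip a geometry by a convex POLYGON; NULL when nothing remains.
## Degenerate (zero-area / lower-dimensional) outputs are dropped.
clip_geom_convex <- function(geom, type, clip_poly) {
  clip_ccw <- ensure_ccw(clip_poly[[1L]])
  if (!is_convex_ring(clip_ccw)) {
    stop("clipping requires a convex query geometry; ",
         "use annot_op = \"keep_whole\" for non-convex queries")
  }
  if (is_pointlike(type)) {
    pts <- geom_points_matrix(geom, type)
    keep <- points_in_polygon(pts, clip_poly) > 0L
    if (!any(keep)) return(NULL)
    kept <- pts[keep, , drop = FALSE]
    if (type == "POINT") return(list(geom = as.numeric(kept[1L, ]), type = "POINT"))
    return(list(geom = kept, type = "MULTIPOINT"))
  }
  if (type == "POLYGON") {
    rings <- lapply(geom, clip_ring_convex, clip_ccw = clip_ccw)
    if (is.null(rings[[1L]])) return(NULL)
    rings <- rings[!vapply(rings, is.null, TRUE)]
    return(list(geom = rings, type = "POLYGON"))
  }
  if (type == "MULTIPOLYGON") {
    parts <- lapply(geom, function(p) clip_geom_convex(p, "POLYGON", clip_poly))
    parts <- parts[!vapply(parts, is.null, TRUE)]
    if (length(parts) == 0L) return(NULL)
    return(list(geom = lapply(parts, `[[`, "geom"), type = "MULTIPOLYGON"))
  }
  stop("clipping LINESTRING layers is not supported")
}
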