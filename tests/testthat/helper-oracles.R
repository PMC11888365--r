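## Independent brute-force oracles. Everything here is implemented from the
## mathematical definitions, sharing no code with the package internals, so
## that agreement between the two is meaningful evidence of correctness.

## ray-casting point-in-ring test: 0 outside, 1 inside, 2 on the boundary
oracle_pip_ring <- function(p, ring, tol = 1e-12) {
  v <- ring[-nrow(ring), , drop = FALSE]
  n <- nrow(v)
  inside <- FALSE
  for (k in seq_len(n)) {
    a <- v[k, ]
    b <- v[k %% n + 1L, ]
    cross <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    if (abs(cross) <= tol * max(1, abs(b[1] - a[1]), abs(b[2] - a[2])) &&
        p[1] >= min(a[1], b[1]) - tol && p[1] <= max(a[1], b[1]) + tol &&
        p[2] >= min(a[2], b[2]) - tol && p[2] <= max(a[2], b[2]) + tol) {
      return(2L)
    }
    if ((a[2] > p[2]) != (b[2] > p[2])) {
      xint <- a[1] + (p[2] - a[2]) * (b[1] - a[1]) / (b[2] - a[2])
      if (p[1] < xint) inside <- !inside
    }
  }
  if (inside) 1L else 0L
}

## POLYGON (list of rings, even-odd) or MULTIPOLYGON
oracle_pip_geom <- function(p, geom, type) {
  rings <- if (type == "POLYGON") geom else unlist(geom, recursive = FALSE)
  codes <- vapply(rings, function(r) oracle_pip_ring(p, r), 0L)
  if (any(codes == 2L)) return(2L)
  if (sum(codes == 1L) %% 2L == 1L) 1L else 0L
}

## canonical "i j" keys (i < j) for comparing undirected edge sets
edge_keys <- function(g) {
  e <- g@edges
  sort(unique(paste(pmin(e$i, e$j), pmax(e$i, e$j))))
}

oracle_knn_keys <- function(pts, k, sym = "union") {
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  pairs <- do.call(rbind, lapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    cbind(i, others[order(d[i, others], others)][seq_len(k)])
  }))
  key <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  if (sym == "union") sort(unique(key))
  else sort(unique(key[duplicated(key)]))
}

oracle_distance_keys <- function(pts, d_max) {
  n <- nrow(pts)
  keys <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (sqrt(sum((pts[i, ] - pts[j, ])^2)) <= d_max) {
        keys <- c(keys, paste(i, j))
      }
    }
  }
  sort(keys)
}

## Gabriel graph from the definition: edge (i, j) iff the open disk with
## diameter ij contains no other point (brute force over all pairs)
oracle_gabriel_keys <- function(pts) {
  n <- nrow(pts)
  keys <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      m <- (pts[i, ] + pts[j, ]) / 2
      r2 <- sum((pts[i, ] - m)^2)
      d2 <- (pts[, 1] - m[1])^2 + (pts[, 2] - m[2])^2
      d2[c(i, j)] <- Inf
      if (all(d2 >= r2)) keys <- c(keys, paste(i, j))
    }
  }
  sort(keys)
}

## Delaunay edges from the empty-circumcircle definition: an edge belongs to
## the triangulation iff it is a side of some triangle whose circumcircle
## contains no other input point (points in general position)
oracle_delaunay_keys <- function(pts, tol = 1e-9) {
  n <- nrow(pts)
  keys <- character(0)
  tri <- utils::combn(n, 3L)
  for (t in seq_len(ncol(tri))) {
    i <- tri[1L, t]; j <- tri[2L, t]; k <- tri[3L, t]
    a <- pts[i, ]; b <- pts[j, ]; cc <- pts[k, ]
    d <- 2 * (a[1] * (b[2] - cc[2]) + b[1] * (cc[2] - a[2]) +
                cc[1] * (a[2] - b[2]))
    if (abs(d) < 1e-12) next  # collinear triple
    ux <- (sum(a^2) * (b[2] - cc[2]) + sum(b^2) * (cc[2] - a[2]) +
             sum(cc^2) * (a[2] - b[2])) / d
    uy <- (sum(a^2) * (cc[1] - b[1]) + sum(b^2) * (a[1] - cc[1]) +
             sum(cc^2) * (b[1] - a[1])) / d
    r2 <- sum((a - c(ux, uy))^2)
    d2 <- (pts[, 1] - ux)^2 + (pts[, 2] - uy)^2
    d2[c(i, j, k)] <- Inf
    if (all(d2 > r2 - tol * r2)) {
      keys <- c(keys, paste(c(i, i, j), c(j, k, k)))
    }
  }
  sort(unique(keys))
}

## closed-rectangle predicate oracles (interval arithmetic)
rect_oracle <- function(r1, r2, predicate) {
  overlap_x <- min(r1[3], r2[3]) - max(r1[1], r2[1])
  overlap_y <- min(r1[4], r2[4]) - max(r1[2], r2[2])
  switch(predicate,
    intersects = overlap_x >= 0 && overlap_y >= 0,
    contains = r2[1] >= r1[1] && r2[3] <= r1[3] &&
               r2[2] >= r1[2] && r2[4] <= r1[4] &&
               overlap_x > 0 && overlap_y > 0,
    within = rect_oracle(r2, r1, "contains"),
    touches = overlap_x >= 0 && overlap_y >= 0 &&
              (overlap_x == 0 || overlap_y == 0))
}

random_rects <- function(n, lim = 10, max_side = 4) {
  t(vapply(seq_len(n), function(i) {
    x0 <- runif(1, 0, lim); y0 <- runif(1, 0, lim)
    c(x0, y0, x0 + runif(1, 0.2, max_side), y0 + runif(1, 0.2, max_side))
  }, numeric(4)))
}

## integer-cornered rectangles exercise exact boundary contact
random_int_rects <- function(n, lim = 8L) {
  t(vapply(seq_len(n), function(i) {
    x0 <- sample.int(lim, 1L) - 1L; y0 <- sample.int(lim, 1L) - 1L
    c(x0, y0, x0 + sample.int(3L, 1L), y0 + sample.int(3L, 1L))
  }, numeric(4)))
}

random_point_layer <- function(n, lim = 100) {
  geometry_layer(lapply(seq_len(n), function(i)
    gf_point(runif(1, 0, lim), runif(1, 0, lim))),
    "POINT", data.frame(id = seq_len(n)))
}

expect_identical_containers <- function(a, b) {
  for (s in methods::slotNames(class(a))) {
    expect_identical(methods::slot(a, s), methods::slot(b, s),
                     label = paste0("slot '", s, "' of the first container"),
                     expected.label = paste0("slot '", s,
                                             "' of the second container"))
  }
}
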