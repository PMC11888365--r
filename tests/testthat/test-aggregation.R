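test_that("square grids tile the extent with the ceiling rule", {
  g <- make_grid(c(0, 0, 10, 7), "square", cellsize = 3)
  ## ceiling(10/3) = 4 columns, ceiling(7/3) = 3 rows
  expect_equal(n_geometries(g), 12L)
  expect_equal(max(g@attrs$grid_col), 4L)
  expect_equal(max(g@attrs$grid_row), 3L)
  areas <- vapply(g@geoms, geom_area, 0, type = "POLYGON")
  expect_equal(areas, rep(9, 12))
  ## cells cover the extent: the grid bbox contains it
  b <- bbox(g)
  expect_true(b@xmin <= 0 && b@ymin <= 0 && b@xmax >= 10 && b@ymax >= 7)
})

test_that("hex grids use flat-topped hexes with the stated spacing", {
  cs <- 6
  g <- make_grid(c(0, 0, 30, 30), "hex", cellsize = cs)
  R <- 2 * cs / 3
  areas <- vapply(g@geoms, geom_area, 0, type = "POLYGON")
  ## regular hexagon area = 3 sqrt(3) / 2 R^2
  expect_equal(areas, rep(3 * sqrt(3) / 2 * R^2, length(areas)),
               tolerance = 1e-12)
  cents <- t(vapply(g@geoms, geom_centroid, numeric(2), type = "POLYGON"))
  ## adjacent columns of centers are cellsize apart horizontally and offset
  ## by half the vertical pitch
  ux <- sort(unique(round(cents[, 1], 9)))
  expect_equal(diff(ux), rep(cs, length(ux) - 1))
  vp <- sqrt(3) * R
  y_even <- cents[round(cents[, 1], 9) == ux[1], 2]
  y_odd <- cents[round(cents[, 1], 9) == ux[2], 2]
  ## even columns sit on integer multiples of the vertical pitch, odd
  ## columns halfway between (y / (vp/2) even vs odd integers)
  expect_equal(round(y_even / (vp / 2)) %% 2, rep(0, length(y_even)))
  expect_equal(y_even, round(y_even / (vp / 2)) * vp / 2, tolerance = 1e-9)
  expect_equal(round(y_odd / (vp / 2)) %% 2, rep(1, length(y_odd)))
  expect_equal(y_odd, round(y_odd / (vp / 2)) * vp / 2, tolerance = 1e-9)
  ## hexes cover the extent
  b <- bbox(g)
  expect_true(b@xmin <= 0 && b@ymin <= 0 && b@xmax >= 30 && b@ymax >= 30)
})

test_that("grid cells have pairwise disjoint interiors", {
  ## squares have exact coordinates: test interior disjointness exactly
  g <- make_grid(c(0, 0, 12, 12), "square", cellsize = 5)
  n <- n_geometries(g)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      expect_false(geofeat:::polygon_interiors_intersect(
        g@geoms[[i]], "POLYGON", g@geoms[[j]], "POLYGON"),
        label = sprintf("square cells %d and %d overlap", i, j))
    }
  }
  ## hex vertices carry floating-point rounding, so adjacent cells may
  ## overlap by a sliver; bound the pairwise intersection area instead
  h <- make_grid(c(0, 0, 12, 12), "hex", cellsize = 5)
  cell_area <- geom_area(h@geoms[[1]], "POLYGON")
  nh <- n_geometries(h)
  for (i in seq_len(nh - 1L)) {
    for (j in seq.int(i + 1L, nh)) {
      ov <- geofeat:::clip_geom_convex(h@geoms[[i]], "POLYGON", h@geoms[[j]])
      if (!is.null(ov)) {
        expect_lt(geom_area(ov$geom, ov$type) / cell_area, 1e-12)
      }
    }
  }
})

test_that("a boundary point is assigned once, to the lowest bin index", {
  g <- make_grid(c(0, 0, 4, 2), "square", cellsize = 2)   # bins 1,2 bottom
  pts <- rbind(c(2, 1),   # on the shared edge of bins 1 and 2
               c(2, 2),   # corner shared by all four bins
               c(1, 1))   # interior of bin 1
  a <- geofeat:::assign_points_to_polygons(pts, g)
  expect_equal(a, c(1L, 1L, 1L))
})

test_that("aggregate_cells(sum) conserves per-gene totals", {
  sfc <- synth_dataset(n_cells = 40, n_genes = 12, seed = 17)
  grid <- make_grid(c(0, 0, 100, 100), "square", cellsize = 25)
  agg <- suppressMessages(aggregate_cells(sfc, grid))
  expect_equal(rowSums(get_assay(agg)), rowSums(get_assay(sfc)))
  expect_equal(n_locations(agg), n_geometries(grid))
  expect_identical(get_geometry(agg, "col", "bins")@geoms, grid@geoms)
  expect_equal(agg@metadata$aggregation$n_dropped, 0L)
  ## same conservation with hexagonal bins
  hexg <- make_grid(c(0, 0, 100, 100), "hex", cellsize = 20)
  hagg <- suppressMessages(aggregate_cells(sfc, hexg))
  expect_equal(rowSums(get_assay(hagg)), rowSums(get_assay(sfc)))
})

test_that("aggregate_cells reports dropped out-of-bin locations", {
  sfc <- synth_dataset(n_cells = 30, n_genes = 4, seed = 23)
  half <- make_grid(c(0, 0, 50, 100), "square", cellsize = 50)
  expect_message(agg <- aggregate_cells(sfc, half), "dropped")
  expect_gt(agg@metadata$n_dropped, 0)
  ## kept + dropped = all cells
  cents <- do.call(rbind, get_geometry(sfc, "col", "centroids")@geoms)
  inside <- sum(cents[, 1] <= 50)
  expect_equal(agg@metadata$n_dropped, 30L - inside)
  expect_equal(sum(get_assay(agg)), sum(get_assay(sfc)[, cents[, 1] <= 50]))
})

test_that("aggregate_cells with fun = mean gives NA for empty bins", {
  sfc <- synth_dataset(n_cells = 10, n_genes = 3, seed = 4)
  grid <- make_grid(c(0, 0, 200, 200), "square", cellsize = 100)
  agg <- suppressMessages(aggregate_cells(sfc, grid, fun = mean))
  a <- get_assay(agg)
  cents <- do.call(rbind, get_geometry(sfc, "col", "centroids")@geoms)
  occupied <- unique(geofeat:::assign_points_to_polygons(cents, grid))
  expect_true(all(is.na(a[, setdiff(seq_len(ncol(a)), occupied)])))
  expect_true(all(!is.na(a[, occupied])))
})

test_that("count_points_in_polygons matches the oracle assignment", {
  set.seed(61)
  n <- 80
  pts <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  labels <- sample(c("a", "b", "c"), n, replace = TRUE)
  ply <- geometry_layer(list(gf_rect(c(0, 0, 5, 10)),
                             gf_rect(c(5, 0, 10, 10)),
                             gf_rect(c(2, 2, 8, 8))), "POLYGON",
                        data.frame(id = 1:3))
  ptl <- geometry_layer(lapply(seq_len(n), function(i)
    gf_point(pts[i, 1], pts[i, 2])), "POINT",
    data.frame(label = labels))
  got <- as.matrix(count_points_in_polygons(ptl, ply))
  want <- matrix(0, 3, 3, dimnames = list(unique(labels), NULL))
  for (i in seq_len(n)) {
    for (p in 1:3) {
      if (oracle_pip_geom(pts[i, ], ply@geoms[[p]], "POLYGON") > 0L) {
        want[labels[i], p] <- want[labels[i], p] + 1
        break   # lowest index wins
      }
    }
  }
  expect_equal(got, want)
  ## every point inside some polygon is counted exactly once
  expect_equal(sum(got), n)
})

test_that("aggregate_transcripts conserves counts and keeps feature order", {
  sfc <- synth_dataset(n_cells = 25, n_genes = 8, seed = 19)
  ## bins covering everything the spots can reach (3 sigma slack and more)
  grid <- make_grid(c(-30, -30, 130, 130), "square", cellsize = 40)
  agg <- aggregate_transcripts(sfc, grid)
  spots <- get_geometry(sfc, "row", "txSpots")
  per_gene <- vapply(spots@geoms, nrow, 0L)
  expect_equal(unname(rowSums(get_assay(agg))), as.numeric(per_gene))
  expect_identical(rownames(get_assay(agg)), rownames(get_assay(sfc)))
  expect_identical(row_meta(agg), row_meta(sfc))
  ## since spot counts equal matrix counts in the fixture, totals agree
  expect_equal(rowSums(get_assay(agg)), rowSums(get_assay(sfc)))
})

test_that("genes without spots yield all-zero rows", {
  cnt <- matrix(c(0, 3), 2, 1, dimnames = list(c("gA", "gB"), "c1"))
  sfc <- new_container(cnt, data.frame(barcode = "c1"),
                       data.frame(feature = c("gA", "gB")))
  spots <- geometry_layer(list(gf_multipoint(matrix(numeric(0), ncol = 2)),
                               gf_multipoint(rbind(c(1, 1), c(2, 2), c(9, 9)))),
                          "MULTIPOINT", data.frame(gene = c("gA", "gB")))
  sfc <- set_geometry(sfc, "row", "txSpots", spots)
  grid <- make_grid(c(0, 0, 4, 4), "square", cellsize = 4)
  agg <- aggregate_transcripts(sfc, grid)
  expect_equal(unname(get_assay(agg)), matrix(c(0, 2), 2, 1))
})

test_that("aggregation parameter validation", {
  sfc <- synth_dataset(n_cells = 5, n_genes = 3, seed = 1)
  expect_error(make_grid(c(0, 0, 1, 1), "square", cellsize = 0),
               "cellsize must be > 0")
  bare <- new_container(matrix(1, 1, 1), data.frame(b = 1), data.frame(g = 1))
  grid <- make_grid(c(0, 0, 1, 1), "square", cellsize = 1)
  expect_error(aggregate_cells(bare, grid), "col geometry")
  expect_error(aggregate_transcripts(bare, grid), "row geometry")
})
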