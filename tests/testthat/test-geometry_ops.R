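## a small container with known coordinates for crop tests
crop_fixture <- function() {
  xs <- c(1, 3, 5, 7, 9)
  cnt <- matrix(1:10, 2, 5,
                dimnames = list(c("g1", "g2"), paste0("c", 1:5)))
  sfc <- new_container(cnt, data.frame(barcode = paste0("c", 1:5)),
                       data.frame(gene = c("g1", "g2")))
  pts <- geometry_layer(lapply(xs, function(x) gf_point(x, 5)), "POINT",
                        data.frame(barcode = paste0("c", 1:5)))
  sfc <- set_geometry(sfc, "col", "centroids", pts)
  ## 2x2 squares centered on the points
  sq <- geometry_layer(lapply(xs, function(x)
    gf_rect(c(x - 1, 4, x + 1, 6))), "POLYGON",
    data.frame(barcode = paste0("c", 1:5)))
  sfc <- set_geometry(sfc, "col", "cells", sq)
  ann <- geometry_layer(list(gf_rect(c(0, 0, 10, 10))), "POLYGON",
                        data.frame(name = "tissue"))
  set_geometry(sfc, "annot", "tissue", ann)
}

test_that("crop keeps the right columns per predicate", {
  sfc <- crop_fixture()
  q <- c(2, 0, 6.5, 10)
  ## points at x = 3, 5 are inside; 1, 7, 9 outside
  out <- crop(sfc, q, "centroids", "intersects")
  expect_equal(col_meta(out)$barcode, c("c2", "c3"))
  expect_equal(get_assay(out), get_assay(sfc)[, 2:3])
  ## squares [0,2], [2,4], [4,6], [6,8] all reach into [2, 6.5]; [8,10] not
  out2 <- crop(sfc, q, "cells", "intersects")
  expect_equal(col_meta(out2)$barcode, c("c1", "c2", "c3", "c4"))
  ## containment: square must lie entirely within the query
  out3 <- crop(sfc, q, "cells", "contains_in")
  expect_equal(col_meta(out3)$barcode, c("c2", "c3"))
  ## covered_by keeps points on the query boundary; contains_in needs an
  ## interior point (points at x = 1, 5 sit exactly on the query edges)
  out4 <- crop(sfc, c(1, 0, 5, 10), "centroids", "covered_by")
  expect_equal(col_meta(out4)$barcode, c("c1", "c2", "c3"))
  out5 <- crop(sfc, c(1, 0, 5, 10), "centroids", "contains_in")
  expect_equal(col_meta(out5)$barcode, "c2")
})

test_that("crop clips annotation geometry to the query", {
  sfc <- crop_fixture()
  out <- crop(sfc, c(2, 1, 6, 8), "centroids", "intersects",
              annot_op = "clip")
  tis <- get_geometry(out, "annot", "tissue")
  expect_equal(geom_area(tis@geoms[[1]], tis@geom_type), 4 * 7)
  b <- bbox(tis)
  expect_equal(c(b@xmin, b@ymin, b@xmax, b@ymax), c(2, 1, 6, 8))
})

test_that("crop keep_whole keeps intersecting annotation geometries intact", {
  sfc <- crop_fixture()
  out <- crop(sfc, c(2, 1, 6, 8), "centroids", "intersects",
              annot_op = "keep_whole")
  tis <- get_geometry(out, "annot", "tissue")
  expect_equal(geom_area(tis@geoms[[1]], tis@geom_type), 100)
})

test_that("crop drops annotation geometries emptied by clipping", {
  sfc <- crop_fixture()
  ann2 <- geometry_layer(list(gf_rect(c(0, 0, 1, 1)),
                              gf_rect(c(8, 8, 10, 10))), "POLYGON",
                         data.frame(name = c("a", "b")))
  sfc <- set_geometry(sfc, "annot", "two", ann2)
  out <- crop(sfc, c(0, 0, 2, 2), "centroids", "intersects",
              annot_op = "clip")
  two <- get_geometry(out, "annot", "two")
  expect_equal(n_geometries(two), 1L)
  expect_equal(two@attrs$name, "a")
})

test_that("crop restricts images to the query window", {
  sfc <- crop_fixture()
  img <- memory_image(matrix(seq_len(100) / 100, 10, 10), c(0, 0, 10, 10))
  sfc <- set_image(sfc, "img", img)
  out <- crop(sfc, c(2, 2, 6, 6), "centroids", "intersects")
  ci <- get_image(out, "img")
  expect_equal(geofeat:::as_extent_vec(ci@extent), c(2, 2, 6, 6))
  expect_equal(dim(ci@pixels)[1:2], c(4L, 4L))
  ## an image disjoint from the query is dropped
  sfc <- set_image(sfc, "far", memory_image(matrix(0.1, 2, 2),
                                            c(50, 50, 60, 60)))
  out2 <- crop(sfc, c(2, 2, 6, 6), "centroids", "intersects")
  expect_error(get_image(out2, "far"), "no image named 'far'")
})

test_that("a disjoint crop query yields a valid zero-location container", {
  sfc <- crop_fixture()
  out <- crop(sfc, c(100, 100, 110, 110), "centroids", "intersects")
  expect_equal(n_locations(out), 0L)
  expect_equal(n_features(out), 2L)
  expect_true(validObject(out))
})

test_that("polygon queries work and non-convex clip queries are rejected", {
  sfc <- crop_fixture()
  tri <- gf_polygon(rbind(c(0, 0), c(6, 0), c(0, 12), c(0, 0)))
  out <- crop(sfc, tri, "centroids", "intersects", annot_op = "keep_whole")
  expect_equal(col_meta(out)$barcode, c("c1", "c2"))
  ## an L-shaped (non-convex) query cannot be used for clipping
  ell <- gf_polygon(rbind(c(0, 0), c(4, 0), c(4, 2), c(2, 2), c(2, 4),
                          c(0, 4), c(0, 0)))
  expect_error(crop(sfc, ell, "centroids", "intersects", annot_op = "clip"),
               "convex")
})

test_that("relate matches the rectangle oracle on seeded random layers", {
  set.seed(99)
  ra <- rbind(random_rects(10), random_int_rects(10))
  rb <- rbind(random_rects(10), random_int_rects(10))
  la <- geometry_layer(apply(ra, 1, gf_rect), "POLYGON",
                       data.frame(id = seq_len(nrow(ra))))
  lb <- geometry_layer(apply(rb, 1, gf_rect), "POLYGON",
                       data.frame(id = seq_len(nrow(rb))))
  for (pred in c("intersects", "contains", "within", "touches")) {
    got <- as.matrix(relate(la, lb, pred))
    want <- outer(seq_len(nrow(ra)), seq_len(nrow(rb)),
                  Vectorize(function(i, j) rect_oracle(ra[i, ], rb[j, ], pred)))
    expect_equal(unname(got), want, label = paste("relate", pred))
  }
  expect_error(relate(la, geometry_layer(list(), "POLYGON",
                                         data.frame()), "intersects"),
               "non-empty")
})

test_that("annot_summary aggregates intersecting annotation attributes", {
  sfc <- crop_fixture()
  ann <- geometry_layer(list(gf_rect(c(0, 0, 4, 10)),    # covers x <= 4
                             gf_rect(c(2, 0, 10, 10))),  # covers x >= 2
                        "POLYGON", data.frame(name = c("L", "R"),
                                              area = c(10, 20)))
  sfc <- set_geometry(sfc, "annot", "regions", ann)
  ## points at x = 1, 3, 5, 7, 9; both regions overlap on [2, 4]
  cnts <- annot_summary(sfc, "regions", "centroids", fun = "count")
  expect_equal(cnts, c(1, 2, 1, 1, 1))
  means <- annot_summary(sfc, "regions", "centroids", "area", "mean")
  expect_equal(means, c(10, 15, 20, 20, 20))
  sums <- annot_summary(sfc, "regions", "centroids", "area", "sum")
  expect_equal(sums, c(10, 30, 20, 20, 20))
  expect_error(annot_summary(sfc, "regions", "centroids", "nope", "mean"),
               "unknown attribute 'nope'")
})

test_that("annot_summary gives NA (or 0 counts) with no intersections", {
  sfc <- crop_fixture()
  ann <- geometry_layer(list(gf_rect(c(50, 50, 60, 60))), "POLYGON",
                        data.frame(name = "far", w = 1))
  sfc <- set_geometry(sfc, "annot", "far", ann)
  expect_true(all(is.na(annot_summary(sfc, "far", "centroids", "w", "mean"))))
  expect_equal(annot_summary(sfc, "far", "centroids", fun = "count"),
               rep(0, 5))
})

test_that("split_by_annotation partitions columns by region", {
  sfc <- synth_dataset(n_cells = 30, n_genes = 5, seed = 13)
  parts <- split_by_annotation(sfc, "regions", "centroids")
  expect_named(parts, c("left", "right"))
  ## centroids are strictly inside one half each (x != 50 almost surely)
  expect_equal(n_locations(parts$left) + n_locations(parts$right), 30L)
  xs <- vapply(get_geometry(parts$left, "col", "centroids")@geoms,
               `[`, 0, 1L)
  expect_true(all(xs <= 50))
  ## a column overlapping both regions appears in both
  sfc2 <- crop_fixture()
  ann <- geometry_layer(list(gf_rect(c(0, 0, 4, 10)),
                             gf_rect(c(2, 0, 10, 10))), "POLYGON",
                        data.frame(name = c("L", "R")))
  sfc2 <- set_geometry(sfc2, "annot", "overlapping", ann)
  parts2 <- split_by_annotation(sfc2, "overlapping", "centroids")
  expect_equal(n_locations(parts2$L) + n_locations(parts2$R), 6L)  # 5 + c2 twice
})
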