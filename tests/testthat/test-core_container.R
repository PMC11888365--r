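make_small <- function(n_genes = 4, n_cells = 6) {
  cnt <- matrix(seq_len(n_genes * n_cells), n_genes, n_cells,
                dimnames = list(paste0("g", seq_len(n_genes)),
                                paste0("c", seq_len(n_cells))))
  new_container(cnt,
                data.frame(barcode = paste0("c", seq_len(n_cells))),
                data.frame(gene = paste0("g", seq_len(n_genes))),
                units = "micron")
}

test_that("construction validates axis alignment with informative errors", {
  cnt <- matrix(1, 3, 4)
  expect_error(new_container(cnt, data.frame(b = 1:5), data.frame(g = 1:3)),
               "location axis mismatch")
  expect_error(new_container(cnt, data.frame(b = 1:4), data.frame(g = 1:2)),
               "feature axis mismatch")
  sfc <- new_container(cnt, data.frame(b = 1:4), data.frame(g = 1:3))
  expect_equal(n_features(sfc), 3)
  expect_equal(n_locations(sfc), 4)
})

test_that("negative counts are rejected", {
  cnt <- matrix(c(1, -2, 3, 4), 2, 2)
  expect_error(new_container(cnt, data.frame(b = 1:2), data.frame(g = 1:2)),
               "negative")
})

test_that("assays are stored as double and retrieved by name", {
  sfc <- make_small()
  expect_type(get_assay(sfc, "counts"), "double")
  sfc <- set_assay(sfc, "lognorm", log1p(get_assay(sfc)))
  expect_equal(get_assay(sfc, "lognorm"), log1p(get_assay(sfc, "counts")))
  expect_error(get_assay(sfc, "nope"), "no assay named 'nope'")
  expect_error(set_assay(sfc, "bad", matrix(1, 2, 2)))
})

test_that("col geometry layers must match the number of locations", {
  sfc <- make_small(4, 6)
  pts5 <- geometry_layer(lapply(1:5, function(i) gf_point(i, i)), "POINT",
                         data.frame(id = 1:5))
  expect_error(set_geometry(sfc, "col", "centroids", pts5),
               "5 geometries but the container has 6 locations")
  pts6 <- geometry_layer(lapply(1:6, function(i) gf_point(i, i)), "POINT",
                         data.frame(id = 1:6))
  sfc <- set_geometry(sfc, "col", "centroids", pts6)
  expect_identical(get_geometry(sfc, "col", "centroids"), pts6)
  expect_error(get_geometry(sfc, "col", "missing"), "no col geometry layer")
})

test_that("row geometry layers must match the number of features", {
  sfc <- make_small(4, 6)
  mp <- geometry_layer(lapply(1:3, function(i)
    gf_multipoint(cbind(i, i))), "MULTIPOINT", data.frame(gene = 1:3))
  expect_error(set_geometry(sfc, "row", "txSpots", mp),
               "3 geometries but the container has 4 features")
})

test_that("annot layers are unconstrained and listed by geometry_names", {
  sfc <- make_small()
  ann <- geometry_layer(list(gf_rect(c(0, 0, 1, 1))), "POLYGON",
                        data.frame(name = "roi"))
  sfc <- set_geometry(sfc, "annot", "roi", ann)
  expect_identical(geometry_names(sfc, "annot"), "roi")
  expect_null(geometry_names(sfc, "col"))
})

test_that("local results enforce row alignment and miss with distinct errors", {
  sfc <- make_small(4, 6)
  m <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("stat", "p_value")))
  sfc <- set_local_result(sfc, "localmoran", "g1", m)
  expect_identical(get_local_result(sfc, "localmoran", "g1"), m)
  expect_error(set_local_result(sfc, "x", "g1", matrix(0, 5, 1)),
               "5 rows but the container has 6 locations")
  expect_error(get_local_result(sfc, "nope", "g1"),
               "no local results for statistic 'nope'")
  expect_error(get_local_result(sfc, "localmoran", "g9"),
               "no results for feature 'g9'")
})

test_that("bbox unions geometry layers and image extents", {
  sfc <- make_small(4, 2)
  pts <- geometry_layer(list(gf_point(1, 2), gf_point(5, 7)), "POINT",
                        data.frame(id = 1:2))
  sfc <- set_geometry(sfc, "col", "centroids", pts)
  b <- bbox(sfc)
  expect_equal(c(b@xmin, b@ymin, b@xmax, b@ymax), c(1, 2, 5, 7))
  sfc <- set_image(sfc, "img",
                   memory_image(matrix(0.5, 2, 2), c(-3, 0, 0, 10)))
  b2 <- bbox(sfc)
  expect_equal(c(b2@xmin, b2@ymin, b2@xmax, b2@ymax), c(-3, 0, 5, 10))
  expect_error(bbox(make_small()), "no geometry layers or images")
})

test_that("subsetting synchronizes assays, metadata, geometries, and results", {
  sfc <- synth_dataset(n_cells = 20, n_genes = 8, seed = 11)
  sfc <- set_local_result(sfc, "localmoran", "gene001",
                          matrix(rnorm(40), 20, 2,
                                 dimnames = list(NULL, c("stat", "p"))))
  sfc <- find_spatial_graph(sfc, "col", "centroids", "knn", list(k = 3))
  J <- c(2L, 5L, 9L, 14L, 20L)
  I <- c(1L, 4L, 8L)
  s <- subset_container(sfc, I, J)
  expect_equal(dim(get_assay(s)), c(3L, 5L))
  expect_equal(get_assay(s), get_assay(sfc)[I, J])
  expect_equal(nrow(col_meta(s)), 5L)
  expect_equal(nrow(row_meta(s)), 3L)
  expect_equal(n_geometries(get_geometry(s, "col", "centroids")), 5L)
  expect_equal(n_geometries(get_geometry(s, "col", "cellSeg")), 5L)
  expect_equal(n_geometries(get_geometry(s, "row", "txSpots")), 3L)
  expect_identical(get_geometry(s, "col", "centroids")@geoms,
                   get_geometry(sfc, "col", "centroids")@geoms[J])
  expect_equal(nrow(get_local_result(s, "localmoran", "gene001")), 5L)
  expect_equal(get_graph(s, "col", "knn")@n_nodes, 5L)
  ## annot layers and images pass through unchanged
  expect_identical(s@annot_geometries, sfc@annot_geometries)
  expect_identical(s@images, sfc@images)
})

test_that("graph subsetting keeps exactly the surviving-node edges", {
  sfc <- synth_dataset(n_cells = 25, n_genes = 4, seed = 2)
  sfc <- find_spatial_graph(sfc, "col", "centroids", "knn", list(k = 4))
  g <- get_graph(sfc, "col", "knn")
  J <- c(1L, 3L, 6L, 10L, 11L, 17L, 23L)
  gs <- get_graph(subset_container(sfc, col_idx = J), "col", "knn")
  expect_true(gs@method_meta$subsetted)
  ## expected: edges of g with both endpoints in J, renumbered
  newid <- match(seq_len(g@n_nodes), J)
  keep <- !is.na(newid[g@edges$i]) & !is.na(newid[g@edges$j])
  expect_setequal(paste(newid[g@edges$i[keep]], newid[g@edges$j[keep]]),
                  paste(gs@edges$i, gs@edges$j))
})

test_that("subset composition law holds", {
  sfc <- synth_dataset(n_cells = 24, n_genes = 10, seed = 5)
  sfc <- find_spatial_graph(sfc, "col", "centroids", "knn", list(k = 3),
                            style = "row_standardized")
  I1 <- seq(1L, 9L); I2 <- c(2L, 5L, 7L)
  J1 <- seq(2L, 20L, by = 2L); J2 <- c(1L, 4L, 8L)
  one_step <- subset_container(sfc, I1[I2], J1[J2])
  two_step <- subset_container(subset_container(sfc, I1, J1), I2, J2)
  expect_identical_containers(one_step, two_step)
})

test_that("the [ operator matches subset_container", {
  sfc <- synth_dataset(n_cells = 10, n_genes = 6, seed = 3)
  expect_identical_containers(sfc[c(1, 3), c(2, 4, 6)],
                              subset_container(sfc, c(1, 3), c(2, 4, 6)))
  expect_identical_containers(sfc[, 1:4],
                              subset_container(sfc, col_idx = 1:4))
})

test_that("bad indices are rejected", {
  sfc <- make_small(4, 6)
  expect_error(subset_container(sfc, col_idx = c(1, 7)), "out of range")
  expect_error(subset_container(sfc, col_idx = c(2, 2)), "duplicate-free")
  expect_error(subset_container(sfc, row_idx = 0), "out of range")
  expect_error(subset_container(sfc, col_idx = c(TRUE, FALSE)),
               "wrong length")
})

test_that("logical indices work and zero-column subsets stay valid", {
  sfc <- make_small(4, 6)
  s <- subset_container(sfc, col_idx = rep(c(TRUE, FALSE), 3))
  expect_equal(n_locations(s), 3L)
  z <- subset_container(sfc, col_idx = integer(0))
  expect_equal(n_locations(z), 0L)
  expect_equal(n_features(z), 4L)
})

test_that("container units are carried and reported", {
  sfc <- make_small()
  expect_equal(container_units(sfc), "micron")
  expect_output(show(sfc), "4 features x 6 locations \\[micron\\]")
})
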