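grid16 <- function(x) round(x * 65535) / 65535   # 16-bit quantization grid

test_that("memory images report dimensions, channels, and extent", {
  img <- memory_image(matrix(0.5, 3, 5), c(0, 0, 10, 6))
  expect_equal(img_width(img), 5L)
  expect_equal(img_height(img), 3L)
  expect_equal(img_channels(img), 1L)
  rgb <- memory_image(array(0.2, c(3, 5, 3)), c(0, 0, 10, 6))
  expect_equal(img_channels(rgb), 3L)
  e <- img_extent(img)
  expect_equal(c(e@xmin, e@ymin, e@xmax, e@ymax), c(0, 0, 10, 6))
})

test_that("16-bit TIFF write/read round-trips grid values bit-exactly", {
  px <- grid16(matrix(runif(48), 6, 8))
  img <- memory_image(px, c(0, 0, 8, 6))
  f <- file.path(tempdir(), "rt.tiff")
  write_image(img, f)
  back <- load_image(f)   # extent from the sidecar
  expect_identical(back@pixels[, , drop = TRUE], px)
  expect_equal(geofeat:::as_extent_vec(back@extent), c(0, 0, 8, 6))
})

test_that("an extent is mandatory when loading", {
  f <- file.path(tempdir(), "noext.png")
  png::writePNG(matrix(0.5, 4, 4), f)
  sc <- paste0(f, ".extent.json")
  if (file.exists(sc)) unlink(sc)
  expect_error(load_image(f), "extent is required")
  img <- load_image(f, c(1, 2, 3, 4))
  expect_equal(geofeat:::as_extent_vec(img@extent), c(1, 2, 3, 4))
})

test_that("lazy loading reads only the header and defers pixels", {
  f <- file.path(tempdir(), "lazy.png")
  png::writePNG(matrix(runif(200), 10, 20), f)
  lz <- load_image(f, c(0, 0, 20, 10), lazy = TRUE)
  expect_s4_class(lz, "LazyImage")
  expect_equal(img_width(lz), 20L)
  expect_equal(img_height(lz), 10L)
  expect_equal(img_channels(lz), 1L)
  expect_identical(materialize(lz)@pixels[, , drop = TRUE], png::readPNG(f))
})

test_that("lazy op queue materializes identically to eager ops", {
  f <- file.path(tempdir(), "queue.png")
  png::writePNG(matrix(runif(300), 15, 20), f)
  seqs <- list(c("mirror_h"), c("transpose", "mirror_v"),
               c("mirror_v", "mirror_h", "transpose", "transpose"))
  for (ops in seqs) {
    lz <- load_image(f, c(0, 0, 20, 15), lazy = TRUE)
    eg <- load_image(f, c(0, 0, 20, 15))
    for (op in ops) {
      lz <- img_axis_op(lz, op)
      eg <- img_axis_op(eg, op)
    }
    expect_identical(lz@queue, ops)
    m <- materialize(lz)
    expect_identical(m@pixels, eg@pixels)
    expect_identical(m@extent, eg@extent)
    ## cached dims track the queue without touching pixels
    expect_equal(c(img_height(lz), img_width(lz)), dim(eg@pixels)[1:2])
  }
})

test_that("axis operations act as the advertised pixel permutations", {
  px <- matrix(1:6 / 6, 2, 3)
  img <- memory_image(px, c(0, 0, 3, 2))
  expect_identical(img_axis_op(img, "mirror_h")@pixels[, , drop = TRUE],
                   px[, 3:1])
  expect_identical(img_axis_op(img, "mirror_v")@pixels[, , drop = TRUE],
                   px[2:1, ])
  ## transpose maps (x, y) -> (y, x): with row 1 on top, the pixel at
  ## spatial (x, y) moves to spatial (y, x)
  tp <- img_axis_op(img, "transpose")
  expect_equal(dim(tp@pixels)[1:2], c(3L, 2L))
  e <- geofeat:::as_extent_vec(tp@extent)
  expect_equal(e[3] - e[1], 2)   # width and height swap about the center
  expect_equal(e[4] - e[2], 3)
  ## verify with the value map: input (col x0.5, row) vs output
  p0 <- extract_pixels(img, geometry_layer(list(gf_point(0.5, 1.5)), "POINT",
                                           data.frame(id = 1)), "mean")
  t_res <- resolve_transform(affine_named("transpose"), img@extent)
  q <- apply_transform(t_res, rbind(c(0.5, 1.5)))
  p1 <- extract_pixels(tp, geometry_layer(list(gf_point(q[1], q[2])), "POINT",
                                          data.frame(id = 1)), "mean")
  expect_identical(p0, p1)
})

test_that("general affine resampling preserves constants and density", {
  img <- memory_image(matrix(0.5, 4, 8), c(0, 0, 8, 4))
  t <- affine_named("rotate", list(angle = 90), center = c(0, 0))
  out <- img_affine(img, t, "nearest")
  expect_equal(dim(out@pixels)[1:2], c(8L, 4L))
  expect_true(all(out@pixels == 0.5))
  e <- geofeat:::as_extent_vec(out@extent)
  expect_equal(e, c(-4, 0, 0, 8))
  ## unresolved transforms are rejected
  expect_error(img_affine(img, affine_named("rotate", list(angle = 10))),
               "resolved")
})

test_that("extract_pixels matches a brute-force pixel scan", {
  set.seed(71)
  px <- matrix(runif(20 * 30), 20, 30)
  img <- memory_image(px, c(0, 0, 30, 20))
  polys <- lapply(1:6, function(k) {
    x0 <- runif(1, 0, 22); y0 <- runif(1, 0, 14)
    gf_rect(c(x0, y0, x0 + runif(1, 2, 8), y0 + runif(1, 2, 6)))
  })
  ply <- geometry_layer(polys, "POLYGON", data.frame(id = 1:6))
  for (fun in c("mean", "sum", "min", "max")) {
    got <- extract_pixels(img, ply, fun)
    want <- vapply(polys, function(pg) {
      vals <- c()
      for (r in 1:20) {
        for (cc in 1:30) {
          ctr <- c(cc - 0.5, 20 - (r - 0.5))
          if (oracle_pip_geom(ctr, pg, "POLYGON") > 0L) {
            vals <- c(vals, px[r, cc])
          }
        }
      }
      if (length(vals) == 0) NA_real_ else match.fun(fun)(vals)
    }, 0)
    expect_equal(got, want, label = paste("extract", fun))
  }
})

test_that("extract_pixels at points picks the containing pixel", {
  px <- matrix(1:12 / 12, 3, 4)   # rows top to bottom
  img <- memory_image(px, c(0, 0, 4, 3))
  pts <- geometry_layer(list(gf_point(0.2, 2.9),   # top-left pixel
                             gf_point(3.9, 0.1),   # bottom-right pixel
                             gf_point(4, 0),       # extreme corner
                             gf_point(1.5, 1.5),   # center pixel (2, 2)
                             gf_point(9, 9)),      # outside
                       "POINT", data.frame(id = 1:5))
  v <- extract_pixels(img, pts, "mean")
  expect_equal(v, c(px[1, 1], px[3, 4], px[3, 4], px[2, 2], NA))
})

test_that("polygons covering no pixel center give NA", {
  img <- memory_image(matrix(0.5, 4, 4), c(0, 0, 4, 4))
  tiny <- geometry_layer(list(gf_rect(c(0.9, 0.9, 1.1, 1.1))), "POLYGON",
                         data.frame(id = 1))   # between centers
  expect_true(is.na(extract_pixels(img, tiny, "mean")))
})

test_that("downsample block-averages and preserves the overall mean", {
  px <- matrix(runif(36), 6, 6)
  img <- memory_image(px, c(0, 0, 6, 6))
  d <- downsample(img, 2)
  expect_equal(dim(d@pixels)[1:2], c(3L, 3L))
  expect_equal(d@pixels[1, 1], mean(px[1:2, 1:2]))
  expect_equal(mean(d@pixels), mean(px))
  expect_identical(d@extent, img@extent)
  ## uneven factor: edge blocks are partial means
  d3 <- downsample(memory_image(px[, 1:5], c(0, 0, 5, 6)), 4)
  expect_equal(dim(d3@pixels)[1:2], c(2L, 2L))
  expect_equal(d3@pixels[2, 2], mean(px[5:6, 5]))
  expect_error(downsample(img, 0), "factor must be >= 1")
})

test_that("crop_image keeps the exact pixel block footprint", {
  px <- matrix(1:24 / 24, 4, 6)
  img <- memory_image(px, c(0, 0, 6, 4))
  out <- crop_image(img, c(1.2, 0.7, 4.9, 3.3))
  ## pixel centers kept: x in {1.5, 2.5, 3.5, 4.5}, y in {1.5, 2.5}
  expect_equal(geofeat:::as_extent_vec(out@extent), c(1, 1, 5, 3))
  expect_identical(out@pixels[, , drop = TRUE], px[2:3, 2:5])
  expect_error(crop_image(img, c(10, 10, 12, 12)), "does not overlap")
})

test_that("multi-channel images survive ops channel-by-channel", {
  arr <- array(runif(60), c(4, 5, 3))
  img <- memory_image(arr, c(0, 0, 5, 4))
  m <- img_axis_op(img, "mirror_h")
  for (k in 1:3) expect_identical(m@pixels[, , k], arr[, 5:1, k])
  pt <- geometry_layer(list(gf_point(2.5, 1.5)), "POINT", data.frame(id = 1))
  v <- extract_pixels(img, pt, "mean")
  expect_equal(dim(v), c(1L, 3L))
  expect_equal(as.numeric(v), arr[3, 3, ])   # center of row 3, column 3
})

test_that("PNG round trip preserves 8-bit grid values", {
  px <- round(matrix(runif(30), 5, 6) * 255) / 255
  img <- memory_image(px, c(0, 0, 6, 5))
  f <- file.path(tempdir(), "rt8.png")
  write_image(img, f)
  expect_identical(load_image(f)@pixels[, , drop = TRUE], px)
})
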