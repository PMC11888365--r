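#' Create an in-memory image layer
#'
#' @param pixels numeric array, `nrow x ncol` or `nrow x ncol x channels`
#'   (row 1 is the top row, `y = ymax`).
#' @param extent a [SpatialExtent-class] (or numeric length-4 vector)
#'   registering the pixel grid to the coordinate system.
#' @return a [MemoryImage-class].
#' @export
memory_image <- function(pixels, extent) {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = dim(pixels))
  new("MemoryImage", pixels = pixels, extent = as_spatial_extent(extent))
}

#' Image dimension accessors
#' @param img an [ImageLayer-class].
#' @name image-accessors
#' @export
setGeneric("img_width", function(img) standardGeneric("img_width"))
#' @rdname image-accessors
#' @export
setGeneric("img_height", function(img) standardGeneric("img_height"))
#' @rdname image-accessors
#' @export
setGeneric("img_channels", function(img) standardGeneric("img_channels"))

#' @rdname image-accessors
setMethod("img_width", "MemoryImage", function(img) dim(img@pixels)[2L])
#' @rdname image-accessors
setMethod("img_height", "MemoryImage", function(img) dim(img@pixels)[1L])
#' @rdname image-accessors
setMethod("img_channels", "MemoryImage", function(img) {
  d <- dim(img@pixels); if (length(d) == 3L) d[3L] else 1L
})
#' @rdname image-accessors
setMethod("img_width", "LazyImage", function(img) img@width)
#' @rdname image-accessors
setMethod("img_height", "LazyImage", function(img) img@height)
#' @rdname image-accessors
setMethod("img_channels", "LazyImage", function(img) img@channels)

#' @rdname image-accessors
#' @export
img_extent <- function(img) img@extent

## ---- reading ----

png_header <- function(path) {
  hdr <- readBin(path, "raw", n = 33L)
  if (length(hdr) < 33L ||
      !identical(hdr[1:8],
                 as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)))) {
    stop("not a PNG file: ", path)
  }
  w <- as.integer(sum(as.integer(hdr[17:20]) * 256^(3:0)))
  h <- as.integer(sum(as.integer(hdr[21:24]) * 256^(3:0)))
  ch <- switch(as.character(as.integer(hdr[26])),
               "0" = 1L, "2" = 3L, "3" = 1L, "4" = 2L, "6" = 4L,
               stop("unsupported PNG color type"))
  list(width = w, height = h, channels = ch)
}

image_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) return("tiff")
  if (ext == "png") return("png")
  stop("unsupported image format '", ext, "' (TIFF and PNG are supported)")
}

read_pixels <- function(path) {
  px <- switch(image_format(path),
    tiff = tiff::readTIFF(path),
    png  = png::readPNG(path))
  if (is.matrix(px)) px <- array(px, dim = dim(px))
  px
}

read_image_header <- function(path) {
  if (image_format(path) == "png") return(png_header(path))
  m <- tiff::readTIFF(path, payload = FALSE)
  if (is.data.frame(m)) m <- as.list(m[1L, ])
  list(width = as.integer(m$width), height = as.integer(m$length),
       channels = as.integer(m$samples.per.pixel %||% 1L))
}

read_extent_sidecar <- function(path) {
  sidecar <- paste0(path, ".extent.json")
  if (!file.exists(sidecar)) return(NULL)
  e <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  spatial_extent(e$xmin, e$ymin, e$xmax, e$ymax)
}

#' Load a raster image registered to the coordinate system
#'
#' With `lazy = TRUE` only the file header is read (dimensions and channel
#' count); pixels stay on disk until [materialize()] or an operation that
#' needs them. The spatial extent is mandatory: pass it, or place a sidecar
#' JSON `<path>.extent.json` with keys `xmin`, `ymin`, `xmax`, `ymax` next to
#' the file.
#'
#' @param path a TIFF or PNG file.
#' @param extent a [SpatialExtent-class] or numeric length-4; `NULL` to read
#'   the sidecar.
#' @param lazy read header only?
#' @return an [ImageLayer-class].
#' @export
load_image <- function(path, extent = NULL, lazy = FALSE) {
  if (!file.exists(path)) stop("image file not found: ", path)
  if (is.null(extent)) {
    extent <- read_extent_sidecar(path)
    if (is.null(extent)) {
      stop("no extent given and no sidecar '", path, ".extent.json' found; ",
           "an extent is required to register the image")
    }
  }
  extent <- as_spatial_extent(extent)
  if (lazy) {
    h <- read_image_header(path)
    new("LazyImage", path = path, width = h$width, height = h$height,
        channels = h$channels, queue = character(0), extent = extent)
  } else {
    memory_image(read_pixels(path), extent)
  }
}

#' Write an image layer to TIFF (16-bit, lossless) or PNG
#'
#' Pixel values are clamped to `[0, 1]` and quantized to the format's bit
#' depth (16 for TIFF, 8 for PNG); values already on that grid round-trip
#' bit-exactly. A sidecar `<path>.extent.json` is written alongside.
#'
#' @param img an [ImageLayer-class] (lazy images are materialized).
#' @param path output file path (.tiff/.tif or .png).
#' @export
write_image <- function(img, path) {
  img <- materialize(img)
  px <- img@pixels
  if (length(dim(px)) == 3L && dim(px)[3L] == 1L) px <- px[, , 1L]
  if (length(dim(px)) == 2L) px <- matrix(px, nrow = dim(img@pixels)[1L])
  if (image_format(path) == "tiff") {
    tiff::writeTIFF(px, path, bits.per.sample = 16L, compression = "deflate")
  } else {
    png::writePNG(px, path)
  }
  e <- as_extent_vec(img@extent)
  jsonlite::write_json(list(xmin = e[1], ymin = e[2], xmax = e[3], ymax = e[4]),
                       paste0(path, ".extent.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

## ---- pixel permutations ----

per_channel <- function(px, f) {
  if (length(dim(px)) == 2L) return(f(px))
  out <- NULL
  for (k in seq_len(dim(px)[3L])) {
    m <- f(px[, , k])
    if (is.null(out)) out <- array(0, dim = c(dim(m), dim(px)[3L]))
    out[, , k] <- m
  }
  out
}

px_mirror_h <- function(px) per_channel(px, function(m) m[, rev(seq_len(ncol(m))), drop = FALSE])
px_mirror_v <- function(px) per_channel(px, function(m) m[rev(seq_len(nrow(m))), , drop = FALSE])
## transpose = the map (x, y) -> (y, x); with row 1 on top this is
## matrix transpose followed by reversing both dimensions
px_transpose <- function(px) per_channel(px, function(m) {
  a <- t(m)
  a[rev(seq_len(nrow(a))), rev(seq_len(ncol(a))), drop = FALSE]
})

apply_pixel_op <- function(px, op) {
  switch(op,
    mirror_h = px_mirror_h(px),
    mirror_v = px_mirror_v(px),
    transpose = px_transpose(px),
    stop("unknown axis op: ", op))
}

#' Materialize an image layer into memory
#'
#' For a lazy image, loads the pixels and applies any queued axis operations
#' in order; the result has an empty queue. In-memory images are returned
#' unchanged.
#'
#' @param img an [ImageLayer-class].
#' @return a [MemoryImage-class].
#' @export
setGeneric("materialize", function(img) standardGeneric("materialize"))

#' @rdname materialize
setMethod("materialize", "MemoryImage", function(img) img)

#' @rdname materialize
setMethod("materialize", "LazyImage", function(img) {
  px <- read_pixels(img@path)
  for (op in img@queue) px <- apply_pixel_op(px, op)
  memory_image(px, img@extent)
})

#' Axis-aligned image operation
#'
#' `mirror_h` reflects across the vertical center line, `mirror_v` across the
#' horizontal center line, `transpose` applies the map (x, y) -> (y, x). For
#' in-memory images the pixel array is permuted; for lazy images the
#' operation is appended to the pending queue and only cached metadata is
#' updated — pixels are not loaded. By default the extent pivots about its
#' own center (mirrors leave it unchanged; transpose swaps width and height
#' about the center).
#'
#' @param img an [ImageLayer-class].
#' @param op `"mirror_h"`, `"mirror_v"`, or `"transpose"`.
#' @param update_extent set `FALSE` when the caller manages the extent (used
#'   by [transform_container()]).
#' @return an [ImageLayer-class] of the same flavor.
#' @export
setGeneric("img_axis_op", function(img, op, update_extent = TRUE)
  standardGeneric("img_axis_op"))

transposed_extent <- function(extent) {
  e <- as_extent_vec(extent)
  cx <- (e[1] + e[3]) / 2; cy <- (e[2] + e[4]) / 2
  w <- e[3] - e[1]; h <- e[4] - e[2]
  spatial_extent(cx - h / 2, cy - w / 2, cx + h / 2, cy + w / 2)
}

#' @rdname img_axis_op
setMethod("img_axis_op", "MemoryImage", function(img, op, update_extent = TRUE) {
  op <- match.arg(op, c("mirror_h", "mirror_v", "transpose"))
  img@pixels <- apply_pixel_op(img@pixels, op)
  if (update_extent && op == "transpose") {
    img@extent <- transposed_extent(img@extent)
  }
  img
})

#' @rdname img_axis_op
setMethod("img_axis_op", "LazyImage", function(img, op, update_extent = TRUE) {
  op <- match.arg(op, c("mirror_h", "mirror_v", "transpose"))
  img@queue <- c(img@queue, op)
  if (op == "transpose") {
    wh <- c(img@width, img@height)
    img@width <- wh[2L]; img@height <- wh[1L]
    if (update_extent) img@extent <- transposed_extent(img@extent)
  }
  img
})

## fractional (row, col) of coordinates; pixel centers at integer indices
coord_to_pixel <- function(img, xy) {
  e <- as_extent_vec(img@extent)
  dx <- (e[3] - e[1]) / img_width(img)
  dy <- (e[4] - e[2]) / img_height(img)
  list(col = (xy[, 1L] - e[1]) / dx + 0.5,
       row = (e[4] - xy[, 2L]) / dy + 0.5)
}

pixel_centers <- function(img, cols = seq_len(img_width(img)),
                          rows = seq_len(img_height(img))) {
  e <- as_extent_vec(img@extent)
  dx <- (e[3] - e[1]) / img_width(img)
  dy <- (e[4] - e[2]) / img_height(img)
  list(x = e[1] + (cols - 0.5) * dx, y = e[4] - (rows - 0.5) * dy)
}

#' Resample an image under a general affine transform
#'
#' The output grid is the axis-aligned bounding box of the transformed extent
#' corners, at approximately the input pixel density. Each output pixel is
#' sampled at the inverse-mapped position of its center; samples falling
#' outside the source image take the value 0.
#'
#' @param img an [ImageLayer-class] (lazy images are materialized first).
#' @param t a resolved, invertible [AffineTransform-class].
#' @param resample `"bilinear"` (default) or `"nearest"`.
#' @return a [MemoryImage-class].
#' @export
img_affine <- function(img, t, resample = c("bilinear", "nearest")) {
  resample <- match.arg(resample)
  if (!t@resolved) stop("transform must be resolved before resampling")
  img <- materialize(img)
  if (is_identity_transform(t)) return(img)
  e <- as_extent_vec(img@extent)
  dx <- (e[3] - e[1]) / img_width(img)
  dy <- (e[4] - e[2]) / img_height(img)
  new_ext <- as_extent_vec(transformed_extent(img@extent, t))
  ## preserve pixel density along each input axis through the linear map
  scale_fac <- sqrt(abs(det(t@M)))
  odx <- dx * scale_fac; ody <- dy * scale_fac
  ncol_out <- max(1L, as.integer(round((new_ext[3] - new_ext[1]) / odx)))
  nrow_out <- max(1L, as.integer(round((new_ext[4] - new_ext[2]) / ody)))
  ti <- invert_transform(t)
  xs <- new_ext[1] + (seq_len(ncol_out) - 0.5) * (new_ext[3] - new_ext[1]) / ncol_out
  ys <- new_ext[4] - (seq_len(nrow_out) - 0.5) * (new_ext[4] - new_ext[2]) / nrow_out
  grid <- cbind(rep(xs, each = nrow_out), rep(ys, times = ncol_out))
  src <- apply_transform(ti, grid)
  cf <- (src[, 1L] - e[1]) / dx + 0.5
  rf <- (e[4] - src[, 2L]) / dy + 0.5
  nch <- img_channels(img)
  px <- img@pixels
  sample_ch <- function(m) {
    if (resample == "nearest") {
      r <- round(rf); cc <- round(cf)
      ok <- r >= 1 & r <= nrow(m) & cc >= 1 & cc <= ncol(m)
      v <- numeric(length(rf))
      v[ok] <- m[cbind(r[ok], cc[ok])]
      v
    } else {
      r0 <- floor(rf); c0 <- floor(cf)
      fr <- rf - r0; fc <- cf - c0
      val_at <- function(r, cc) {
        ok <- r >= 1 & r <= nrow(m) & cc >= 1 & cc <= ncol(m)
        v <- numeric(length(r))
        v[ok] <- m[cbind(r[ok], cc[ok])]
        v
      }
      val_at(r0, c0) * (1 - fr) * (1 - fc) +
        val_at(r0 + 1, c0) * fr * (1 - fc) +
        val_at(r0, c0 + 1) * (1 - fr) * fc +
        val_at(r0 + 1, c0 + 1) * fr * fc
    }
  }
  if (nch == 1L) {
    m <- if (length(dim(px)) == 3L) px[, , 1L] else px
    out <- array(sample_ch(m), dim = c(nrow_out, ncol_out))
  } else {
    out <- array(0, dim = c(nrow_out, ncol_out, nch))
    for (k in seq_len(nch)) out[, , k] <- sample_ch(px[, , k])
  }
  memory_image(out, spatial_extent(new_ext))
}

#' Summarize image pixels under geometries
#'
#' For polygonal geometries, `fun` is applied over all pixels whose centers
#' fall inside or on the polygon; for points, the value of the containing
#' pixel is returned. Geometries entirely outside the extent (or covering no
#' pixel center) yield `NA`.
#'
#' @param img an [ImageLayer-class] (materialized automatically).
#' @param geoms a POINT, POLYGON, or MULTIPOLYGON [GeometryLayer-class].
#' @param fun `"mean"`, `"sum"`, `"min"`, or `"max"`.
#' @return for single-channel images a numeric vector (one value per
#'   geometry); otherwise a matrix `n_geometries x channels`.
#' @export
extract_pixels <- function(img, geoms, fun = c("mean", "sum", "min", "max")) {
  fun <- match.arg(fun)
  f <- match.fun(fun)
  img <- materialize(img)
  px <- img@pixels
  nch <- img_channels(img)
  get_ch <- function(k) if (length(dim(px)) == 3L) px[, , k] else px
  n <- n_geometries(geoms)
  out <- matrix(NA_real_, n, nch)
  e <- as_extent_vec(img@extent)
  W <- img_width(img); H <- img_height(img)
  for (g in seq_len(n)) {
    geom <- geoms@geoms[[g]]
    type <- geoms@geom_type
    if (type == "POINT") {
      dx <- (e[3] - e[1]) / W; dy <- (e[4] - e[2]) / H
      cc <- as.integer(floor((geom[1L] - e[1]) / dx)) + 1L
      r <- as.integer(floor((e[4] - geom[2L]) / dy)) + 1L
      if (geom[1L] == e[3]) cc <- W   # right edge belongs to last column
      if (geom[2L] == e[2]) r <- H    # bottom edge belongs to last row
      if (r >= 1L && r <= H && cc >= 1L && cc <= W) {
        for (k in seq_len(nch)) out[g, k] <- get_ch(k)[r, cc]
      }
    } else if (is_polygonal(type)) {
      bb <- geom_bbox(geom, type)
      pc <- pixel_centers(img)
      cols <- which(pc$x >= bb[1L] & pc$x <= bb[3L])
      rows <- which(pc$y >= bb[2L] & pc$y <= bb[4L])
      if (length(cols) == 0L || length(rows) == 0L) next
      pts <- cbind(rep(pc$x[cols], each = length(rows)),
                   rep(pc$y[rows], times = length(cols)))
      inside <- points_in_polygeom(pts, geom, type) > 0L
      if (!any(inside)) next
      ridx <- rep(rows, times = length(cols))[inside]
      cidx <- rep(cols, each = length(rows))[inside]
      for (k in seq_len(nch)) {
        out[g, k] <- f(get_ch(k)[cbind(ridx, cidx)])
      }
    } else {
      stop("extract_pixels supports POINT and polygonal layers only")
    }
  }
  if (nch == 1L) out[, 1L] else out
}

#' Downsample an image by block averaging
#'
#' Pixels are averaged over `factor x factor` blocks (edge blocks may be
#' partial); the extent is unchanged.
#'
#' @param img an [ImageLayer-class].
#' @param factor integer `>= 1`.
#' @return a [MemoryImage-class].
#' @export
downsample <- function(img, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  img <- materialize(img)
  if (factor == 1L) return(img)
  block <- function(m) {
    ri <- ceiling(seq_len(nrow(m)) / factor)
    ci <- ceiling(seq_len(ncol(m)) / factor)
    sums <- rowsum(m, ri)
    sums <- t(rowsum(t(sums), ci))
    cnt <- outer(tabulate(ri), tabulate(ci))
    unname(sums / cnt)
  }
  img@pixels <- per_channel(img@pixels, block)
  img
}

#' Crop an image to an extent
#'
#' Keeps pixels whose centers fall inside the intersection of `extent` with
#' the image extent; the new extent is the exact footprint of the retained
#' pixel block.
#'
#' @param img an [ImageLayer-class].
#' @param extent a [SpatialExtent-class] or numeric length-4 vector.
#' @return a [MemoryImage-class].
#' @export
crop_image <- function(img, extent) {
  q <- as_extent_vec(extent)
  e <- as_extent_vec(img_extent(img))
  clip <- c(max(q[1], e[1]), max(q[2], e[2]), min(q[3], e[3]), min(q[4], e[4]))
  if (clip[1] >= clip[3] || clip[2] >= clip[4]) {
    stop("crop extent does not overlap the image extent")
  }
  img <- materialize(img)
  pc <- pixel_centers(img)
  cols <- which(pc$x >= clip[1] & pc$x <= clip[3])
  rows <- which(pc$y >= clip[2] & pc$y <= clip[4])
  if (length(cols) == 0L || length(rows) == 0L) {
    stop("crop extent covers no pixel centers")
  }
  dx <- (e[3] - e[1]) / img_width(img)
  dy <- (e[4] - e[2]) / img_height(img)
  new_ext <- spatial_extent(e[1] + (min(cols) - 1L) * dx,
                            e[4] - max(rows) * dy,
                            e[1] + max(cols) * dx,
                            e[4] - (min(rows) - 1L) * dy)
  img@pixels <- per_channel(img@pixels,
                            function(m) m[rows, cols, drop = FALSE])
  img@extent <- new_ext
  img
}
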