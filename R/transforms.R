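#' Construct an affine transform from matrix and translation
#'
#' @param M 2x2 invertible matrix.
#' @param v length-2 translation (default zero).
#' @return an [AffineTransform-class], applied to points as `p' = M p + v`.
#' @export
affine_transform <- function(M, v = c(0, 0)) {
  new("AffineTransform", M = matrix(as.numeric(M), 2L, 2L),
      v = as.numeric(v), resolved = TRUE, kind = "matrix", params = list())
}

#' Named affine transforms
#'
#' Convenience constructors for the common map operations. `mirror_h`
#' reflects across a vertical line, `mirror_v` across a horizontal line,
#' `transpose` swaps x and y (matrix `[[0,1],[1,0]]`), all about a pivot
#' point. `rotate` takes an angle in degrees (counter-clockwise); `scale`
#' takes `factor` (or `sx`/`sy`); `translate` takes `dx`, `dy`.
#'
#' Pivoting transforms default to `center = "bbox"`, the center of the
#' container bounding box, resolved at application time by
#' [transform_container()] so the data footprint stays in place; pass a
#' numeric `c(x, y)` to pivot elsewhere.
#'
#' @param kind one of `"mirror_h"`, `"mirror_v"`, `"transpose"`,
#'   `"translate"`, `"scale"`, `"rotate"`.
#' @param params named list: `dx`/`dy` for translate; `factor` or `sx`/`sy`
#'   for scale; `angle` (degrees) for rotate.
#' @param center numeric `c(x, y)` pivot, or `"bbox"` (deferred).
#' @return an [AffineTransform-class] (unresolved when `center = "bbox"`).
#' @examples
#' T <- affine_named("rotate", list(angle = 90), center = c(0, 0))
#' apply_transform(T, rbind(c(1, 0)))  # -> (0, 1)
#' @export
affine_named <- function(kind = c("mirror_h", "mirror_v", "transpose",
                                  "translate", "scale", "rotate"),
                         params = list(), center = "bbox") {
  kind <- match.arg(kind)
  if (kind == "translate") {
    dx <- params$dx %||% 0; dy <- params$dy %||% 0
    return(affine_named_build("translate", list(dx = dx, dy = dy), c(0, 0)))
  }
  if (kind == "scale") {
    sx <- params$sx %||% params$factor %||% 1
    sy <- params$sy %||% params$factor %||% 1
    if (sx == 0 || sy == 0) stop("scale factor must be nonzero")
    params <- list(sx = sx, sy = sy)
  }
  if (kind == "rotate") {
    params <- list(angle = params$angle %||% 0)
  }
  if (identical(center, "bbox")) {
    new("AffineTransform", M = diag(2), v = c(0, 0), resolved = FALSE,
        kind = kind, params = params)
  } else {
    affine_named_build(kind, params, as.numeric(center))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

affine_named_build <- function(kind, params, ctr) {
  M <- switch(kind,
    mirror_h  = matrix(c(-1, 0, 0, 1), 2L, 2L),
    mirror_v  = matrix(c(1, 0, 0, -1), 2L, 2L),
    transpose = matrix(c(0, 1, 1, 0), 2L, 2L),
    translate = diag(2),
    scale     = diag(c(params$sx, params$sy)),
    rotate    = {
      th <- params$angle * pi / 180
      matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
    })
  v <- if (kind == "translate") c(params$dx, params$dy)
       else as.numeric(ctr - M %*% ctr)
  t <- affine_transform(M, v)
  t@kind <- kind
  t@params <- params
  t
}

#' Resolve a deferred-pivot named transform against a bounding box
#'
#' @param t an [AffineTransform-class].
#' @param extent a [SpatialExtent-class] whose center becomes the pivot.
#' @return a resolved [AffineTransform-class].
#' @export
resolve_transform <- function(t, extent) {
  if (t@resolved) return(t)
  e <- as_extent_vec(extent)
  affine_named_build(t@kind, t@params, c((e[1] + e[3]) / 2, (e[2] + e[4]) / 2))
}

#' Apply a transform to coordinates
#'
#' @param t a resolved [AffineTransform-class].
#' @param coords numeric n x 2 matrix.
#' @return transformed n x 2 matrix.
#' @export
apply_transform <- function(t, coords) {
  if (!t@resolved) {
    stop("transform has a deferred 'bbox' pivot; resolve it against an extent ",
         "first (resolve_transform) or apply it via transform_container")
  }
  coords <- matrix(as.numeric(coords), ncol = 2L)
  sweep(coords %*% t(t@M), 2L, t@v, "+")
}

#' Invert an affine transform
#' @param t a resolved [AffineTransform-class].
#' @export
invert_transform <- function(t) {
  if (!t@resolved) stop("cannot invert an unresolved transform")
  Mi <- solve(t@M)
  affine_transform(Mi, -as.numeric(Mi %*% t@v))
}

is_identity_transform <- function(t) {
  t@resolved && identical(t@M, diag(2)) && all(t@v == 0)
}

#' Transform a geometry layer
#' @param layer a [GeometryLayer-class].
#' @param t a resolved [AffineTransform-class].
#' @export
transform_layer <- function(layer, t) {
  if (is_identity_transform(t)) return(layer)
  f <- function(co) apply_transform(t, co)
  layer@geoms <- lapply(layer@geoms, map_geom_coords, type = layer@geom_type,
                        f = f)
  if (det(t@M) < 0 && layer@geom_type %in% c("POLYGON", "MULTIPOLYGON")) {
    ## reflections reverse ring orientation; keep exteriors CCW-consistent
    layer@geoms <- lapply(layer@geoms, map_geom_coords,
                          type = layer@geom_type,
                          f = function(r) r[rev(seq_len(nrow(r))), , drop = FALSE])
  }
  layer
}

#' Transform an entire container
#'
#' Applies the transform to every geometry coordinate in every col/row/annot
#' layer and to every image, keeping all layers mutually aligned. Images
#' under axis-aligned transforms (diagonal or anti-diagonal linear part:
#' mirrors, transpose, scaling, translation) only have their pixel array
#' permuted and extent remapped — no resampling; a general affine resamples
#' via [img_affine()]. A transform created with `center = "bbox"` is resolved
#' against [bbox()] of the container first.
#'
#' @param c a [SpatialFeatureContainer-class].
#' @param t an [AffineTransform-class].
#' @return the transformed container.
#' @export
transform_container <- function(c, t) {
  if (!t@resolved) t <- resolve_transform(t, bbox(c))
  if (abs(det(t@M)) < 1e-12) stop("transform is not invertible")
  if (is_identity_transform(t)) return(c)
  for (axis in c("col", "row", "annot")) {
    sl <- geom_slot(axis)
    slot(c, sl) <- lapply(slot(c, sl), transform_layer, t = t)
  }
  c@images <- lapply(c@images, transform_image, t = t)
  c
}

## ---- images under affine maps ----

transformed_extent <- function(extent, t) {
  e <- as_extent_vec(extent)
  corners <- rbind(c(e[1], e[2]), c(e[3], e[2]), c(e[3], e[4]), c(e[1], e[4]))
  tc <- apply_transform(t, corners)
  spatial_extent(min(tc[, 1L]), min(tc[, 2L]), max(tc[, 1L]), max(tc[, 2L]))
}

## classify the linear part: "diag" (mirrors/scale), "antidiag" (transpose
## family), or "general"
linear_kind <- function(M, tol = 1e-12) {
  if (abs(M[1, 2]) <= tol && abs(M[2, 1]) <= tol) return("diag")
  if (abs(M[1, 1]) <= tol && abs(M[2, 2]) <= tol) return("antidiag")
  "general"
}

#' Transform an image layer
#'
#' Axis-aligned transforms (diagonal or anti-diagonal linear part) permute
#' the pixel array and remap the extent without resampling — on lazy images
#' they only queue pixel operations; a general affine resamples via
#' [img_affine()] with bilinear interpolation.
#'
#' @param img an [ImageLayer-class].
#' @param t a resolved [AffineTransform-class].
#' @return an [ImageLayer-class].
#' @export
transform_image <- function(img, t) {
  if (!t@resolved) {
    stop("transform has a deferred 'bbox' pivot; resolve it against an ",
         "extent first (resolve_transform)")
  }
  kind <- linear_kind(t@M)
  if (kind == "general") {
    return(img_affine(img, t, resample = "bilinear"))
  }
  new_ext <- transformed_extent(img@extent, t)
  if (kind == "diag") {
    ## x' = a x, y' = d y: negative a flips columns, negative d flips rows
    ops <- character(0)
    if (t@M[1, 1] < 0) ops <- c(ops, "mirror_h")
    if (t@M[2, 2] < 0) ops <- c(ops, "mirror_v")
  } else {
    ## x' = b y, y' = c x: transpose, then sign flips
    ops <- "transpose"
    if (t@M[1, 2] < 0) ops <- c(ops, "mirror_h")
    if (t@M[2, 1] < 0) ops <- c(ops, "mirror_v")
  }
  img <- queue_or_apply_ops(img, ops)
  set_img_extent(img, new_ext)
}

set_img_extent <- function(img, extent) {
  img@extent <- as_spatial_extent(extent)
  img
}

queue_or_apply_ops <- function(img, ops) {
  for (op in ops) img <- img_axis_op(img, op, update_extent = FALSE)
  img
}
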