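## Deterministic synthetic datasets. All generators are pure functions of
## their arguments: the RNG state is saved, seeded, and restored.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## outward miter offset of a convex CCW ring (approximate buffer; adequate
## for a fixture boundary that only has to contain the cells)
offset_convex_ring <- function(ring, d) {
  v <- ring[-nrow(ring), , drop = FALSE]
  n <- nrow(v)
  out <- v
  for (i in seq_len(n)) {
    p_prev <- v[(i - 2L) %% n + 1L, ]
    p <- v[i, ]
    p_next <- v[i %% n + 1L, ]
    ## outward normals of the two adjacent edges (CCW ring: outward = right)
    e1 <- p - p_prev; e2 <- p_next - p
    n1 <- c(e1[2L], -e1[1L]); n1 <- n1 / sqrt(sum(n1^2))
    n2 <- c(e2[2L], -e2[1L]); n2 <- n2 / sqrt(sum(n2^2))
    nm <- n1 + n2
    nm <- nm / sqrt(sum(nm^2))
    ## miter length so both edges are displaced by d
    out[i, ] <- p + nm * (d / sqrt((1 + sum(n1 * n2)) / 2))
  }
  close_ring(out)
}

## 16-bit quantization grid used by the TIFF serialization
quantize16 <- function(x) round(x * 65535) / 65535

#' Generate a synthetic spatial dataset
#'
#' A deterministic, fully populated container for testing and examples:
#' uniform cell centroids in the extent; cell polygons as Voronoi cells
#' clipped to the extent; counts drawn per gene as independent Poisson with
#' per-gene means log-uniform on `[0.1, 20]`; per-gene transcript multipoints
#' obtained by scattering each cell's count of each gene as Gaussian offsets
#' (sd = 2% of the extent width) around its centroid, so the number of spots
#' of a gene equals its total count; one tissue-boundary annotation polygon
#' (convex hull of the centroids expanded outward by 3 sd); a `"regions"`
#' annotation layer splitting the extent into left/right halves; and one
#' smooth-gradient grayscale image over the extent (pre-quantized to the
#' 16-bit grid so image serialization is bit-exact). The same seed yields a
#' bit-identical container.
#'
#' @param n_cells number of cells (`>= 3`, Voronoi needs 3).
#' @param n_genes number of genes.
#' @param extent a [SpatialExtent-class] or numeric length-4 (default
#'   `(0, 0, 100, 100)`).
#' @param seed integer RNG seed.
#' @param region_fold_change optional demo knob: multiplies the Poisson mean
#'   of the first half of the genes by this factor for cells in the right
#'   half of the extent (default 1, no regional effect).
#' @return a [SpatialFeatureContainer-class] with col geometries
#'   `"centroids"` and `"cellSeg"`, row geometry `"txSpots"`, annot layers
#'   `"tissue"` and `"regions"`, and image `"gradient"`.
#' @export
synth_dataset <- function(n_cells = 50, n_genes = 20,
                          extent = c(0, 0, 100, 100), seed = 1L,
                          region_fold_change = 1) {
  if (n_cells < 3L) stop("n_cells must be >= 3 (Voronoi tessellation)")
  e <- as_extent_vec(extent)
  with_seed(seed, {
    w <- e[3] - e[1]; h <- e[4] - e[2]
    cx <- stats::runif(n_cells, e[1], e[3])
    cy <- stats::runif(n_cells, e[2], e[4])
    mu <- exp(stats::runif(n_genes, log(0.1), log(20)))
    lambda <- matrix(rep(mu, n_cells), n_genes, n_cells)
    if (region_fold_change != 1) {
      right <- cx > (e[1] + e[3]) / 2
      up <- seq_len(n_genes) <= n_genes %/% 2L
      lambda[up, right] <- lambda[up, right] * region_fold_change
    }
    counts <- matrix(stats::rpois(n_genes * n_cells, lambda),
                     n_genes, n_cells)
    genes <- sprintf("gene%03d", seq_len(n_genes))
    cells <- sprintf("cell%03d", seq_len(n_cells))
    dimnames(counts) <- list(genes, cells)
    sfc <- new_container(counts,
                         data.frame(barcode = cells, sample_id = "sample01"),
                         data.frame(feature = genes,
                                    symbol = toupper(genes)),
                         units = "micron")
    cent <- geometry_layer(lapply(seq_len(n_cells),
                                  function(i) gf_point(cx[i], cy[i])),
                           "POINT", data.frame(barcode = cells))
    sfc <- set_geometry(sfc, "col", "centroids", cent)
    ## Voronoi cell polygons clipped to the extent
    dd <- deldir::deldir(cx, cy, rw = e[c(1, 3, 2, 4)], suppressMsge = TRUE)
    tiles <- deldir::tile.list(dd)
    polys <- lapply(tiles, function(tl) gf_polygon(cbind(tl$x, tl$y)))
    ## tile.list preserves input point order
    sfc <- set_geometry(sfc, "col", "cellSeg",
                        geometry_layer(polys, "POLYGON",
                                       data.frame(barcode = cells)))
    ## transcript spots: counts[g, i] Gaussian offsets around centroid i
    sigma <- 0.02 * w
    spots <- lapply(seq_len(n_genes), function(g) {
      k <- counts[g, ]
      tot <- sum(k)
      if (tot == 0L) return(gf_multipoint(matrix(numeric(0), ncol = 2L)))
      px <- rep(cx, k) + stats::rnorm(tot, 0, sigma)
      py <- rep(cy, k) + stats::rnorm(tot, 0, sigma)
      gf_multipoint(cbind(px, py))
    })
    sfc <- set_geometry(sfc, "row", "txSpots",
                        geometry_layer(spots, "MULTIPOINT",
                                       data.frame(gene = genes)))
    ## tissue boundary: convex hull of centroids, expanded by 3 sigma
    hull <- grDevices::chull(cx, cy)
    ring <- ensure_ccw(close_ring(cbind(cx[hull], cy[hull])))
    sfc <- set_geometry(sfc, "annot", "tissue",
                        geometry_layer(list(gf_polygon(
                          offset_convex_ring(ring, 3 * sigma))),
                          "POLYGON", data.frame(name = "tissue")))
    ## two annotation regions: left / right halves of the extent
    xm <- (e[1] + e[3]) / 2
    regions <- geometry_layer(
      list(gf_rect(c(e[1], e[2], xm, e[4])),
           gf_rect(c(xm, e[2], e[3], e[4]))),
      "POLYGON", data.frame(name = c("left", "right")))
    sfc <- set_geometry(sfc, "annot", "regions", regions)
    ## smooth diagonal gradient image, on the 16-bit grid
    nr <- 64L; nc <- 64L
    gx <- (seq_len(nc) - 0.5) / nc
    gy <- (seq_len(nr) - 0.5) / nr
    grad <- quantize16(outer(rev(gy), gx, function(a, b) (a + b) / 2))
    sfc <- set_image(sfc, "gradient", memory_image(grad, e))
    sfc
  })
}

#' Write a synthetic Visium-style directory
#'
#' Creates a complete Space Ranger >= 2.0-dialect directory readable by
#' [read_visium_like()]: a hex-packed spot array (`n_spots_row` rows of
#' `n_spots_row` spots, 130 full-res-pixel pitch), Poisson counts in
#' MatrixMarket form, `tissue_positions.csv`, `scalefactors_json.json` with
#' `spot_diameter_fullres = 100` and `tissue_lowres_scalef` chosen so the
#' low-res PNG is at most 200 pixels wide, and a diagonal-gradient grayscale
#' PNG whose value at full-res point (x, y-up) is
#' `0.1 + 0.8 * (x / W + y / H) / 2`. The same seed yields byte-identical
#' files.
#'
#' @param n_spots_row spots per row (and number of rows).
#' @param n_genes number of genes.
#' @param seed integer RNG seed.
#' @param outdir output directory (created).
#' @return `outdir`, invisibly.
#' @export
synth_visium_dir <- function(n_spots_row = 6, n_genes = 10, seed = 1L,
                             outdir) {
  dir.create(file.path(outdir, "filtered_feature_bc_matrix"),
             recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "spatial"), showWarnings = FALSE)
  pitch <- 130
  spot_d <- 100
  with_seed(seed, {
    ## hex-packed array: odd array rows shifted by half the column pitch
    ar <- rep(seq_len(n_spots_row) - 1L, each = n_spots_row)
    ac0 <- rep(seq_len(n_spots_row) - 1L, times = n_spots_row)
    ac <- 2L * ac0 + ar %% 2L          # Visium-style even/odd column parity
    margin <- pitch
    px_col <- margin + ac * (pitch / 2)
    px_row <- margin + ar * (pitch * sqrt(3) / 2)
    full_w <- max(px_col) + margin
    full_h <- max(px_row) + margin
    n_spots <- length(px_col)
    barcodes <- sprintf("BC%04d-1", seq_len(n_spots))
    genes <- sprintf("GENE%03d", seq_len(n_genes))
    mu <- exp(stats::runif(n_genes, log(0.5), log(10)))
    counts <- matrix(stats::rpois(n_genes * n_spots, rep(mu, n_spots)),
                     n_genes, n_spots)
    Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                "generalMatrix"),
                    file.path(outdir, "filtered_feature_bc_matrix",
                              "matrix.mtx"))
    writeLines(barcodes, file.path(outdir, "filtered_feature_bc_matrix",
                                   "barcodes.tsv"))
    writeLines(paste(genes, tolower(genes), "Gene Expression", sep = "\t"),
               file.path(outdir, "filtered_feature_bc_matrix",
                         "features.tsv"))
    pos <- data.frame(barcode = barcodes, in_tissue = 1L,
                      array_row = ar, array_col = ac,
                      pxl_row_in_fullres = px_row,
                      pxl_col_in_fullres = px_col)
    utils::write.csv(pos, file.path(outdir, "spatial",
                                    "tissue_positions.csv"),
                     row.names = FALSE, quote = FALSE)
    ## low-res image at most 200 px wide
    lw <- 200L
    scalef <- lw / full_w
    lh <- as.integer(round(full_h * scalef))
    sf <- list(spot_diameter_fullres = spot_d,
               tissue_lowres_scalef = scalef,
               fiducial_diameter_fullres = 1.5 * spot_d)
    jsonlite::write_json(sf, file.path(outdir, "spatial",
                                       "scalefactors_json.json"),
                         auto_unbox = TRUE, digits = NA)
    ## gradient in the full-res y-up frame; PNG row 1 is the top (y = H)
    xs <- ((seq_len(lw) - 0.5) / lw)              # x / W
    ys <- rev((seq_len(lh) - 0.5) / lh)           # y / H, top row first
    img <- outer(ys, xs, function(a, b) 0.1 + 0.8 * (a + b) / 2)
    png::writePNG(img, file.path(outdir, "spatial",
                                 "tissue_lowres_image.png"))
  })
  invisible(outdir)
}
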