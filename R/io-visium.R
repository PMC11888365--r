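find_matrix_file <- function(dir, base) {
  for (f in c(file.path(dir, base), file.path(dir, paste0(base, ".gz")))) {
    if (file.exists(f)) return(f)
  }
  stop("missing file: ", file.path(dir, base), "[.gz]")
}

read_tsv_nohdr <- function(path, col_names) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  names(df) <- col_names[seq_len(ncol(df))]
  df
}

#' Read a Visium-style Space Ranger output directory
#'
#' Expects the Space Ranger >= 2.0 layout:
#' `filtered_feature_bc_matrix/{matrix.mtx, barcodes.tsv, features.tsv}`
#' (each optionally gzipped), `spatial/tissue_positions.csv` (with header
#' `barcode,in_tissue,array_row,array_col,pxl_row_in_fullres,pxl_col_in_fullres`),
#' `spatial/scalefactors_json.json` (including `spot_diameter_fullres` and
#' `tissue_lowres_scalef`), and `spatial/tissue_lowres_image.png`. The older
#' headerless `tissue_positions_list.csv` dialect is rejected.
#'
#' The container is built in full-resolution pixel units. Spot centroids use
#' `x = pxl_col_in_fullres`; with `y_convention = "up"` (default) the pixel
#' row coordinate is flipped to y-up using the full-resolution image height
#' (low-res PNG height divided by `tissue_lowres_scalef`), and the low-res
#' image is registered with extent `(0, 0, width_fullres, height_fullres)`
#' so image and spots stay aligned. Two col geometries are attached:
#' `"centroids"` (points) and `"spotPoly"` (each centroid buffered to a
#' regular 32-gon of radius `spot_diameter_fullres / 2`; the 32-gon's area
#' falls short of the true disc by about 0.64%).
#'
#' @param dir Space Ranger-style directory.
#' @param y_convention `"up"` (flip to y-up, default) or `"down"` (keep raw
#'   pixel rows).
#' @return a [SpatialFeatureContainer-class], `units = "full_res_pixel"`.
#' @export
read_visium_like <- function(dir, y_convention = c("up", "down")) {
  y_convention <- match.arg(y_convention)
  mdir <- file.path(dir, "filtered_feature_bc_matrix")
  if (!dir.exists(mdir)) stop("missing directory: ", mdir)
  f_mtx <- find_matrix_file(mdir, "matrix.mtx")
  f_bc <- find_matrix_file(mdir, "barcodes.tsv")
  f_ft <- find_matrix_file(mdir, "features.tsv")
  f_pos <- file.path(dir, "spatial", "tissue_positions.csv")
  if (!file.exists(f_pos)) {
    old <- file.path(dir, "spatial", "tissue_positions_list.csv")
    if (file.exists(old)) {
      stop("found the pre-2.0 headerless 'tissue_positions_list.csv'; ",
           "this reader supports the Space Ranger >= 2.0 ",
           "'tissue_positions.csv' dialect only")
    }
    stop("missing file: ", f_pos)
  }
  f_sf <- file.path(dir, "spatial", "scalefactors_json.json")
  if (!file.exists(f_sf)) stop("missing file: ", f_sf)
  f_img <- file.path(dir, "spatial", "tissue_lowres_image.png")
  if (!file.exists(f_img)) stop("missing file: ", f_img)

  counts <- as.matrix(Matrix::readMM(f_mtx))
  barcodes <- read_tsv_nohdr(f_bc, "barcode")$barcode
  feats <- read_tsv_nohdr(f_ft, c("feature", "symbol", "feature_type"))
  if (length(barcodes) != ncol(counts)) {
    stop(sprintf("barcodes.tsv has %d entries but the matrix has %d columns",
                 length(barcodes), ncol(counts)))
  }
  if (nrow(feats) != nrow(counts)) {
    stop(sprintf("features.tsv has %d entries but the matrix has %d rows",
                 nrow(feats), nrow(counts)))
  }
  dimnames(counts) <- list(feats$feature, barcodes)

  pos <- utils::read.csv(f_pos, stringsAsFactors = FALSE)
  need_cols <- c("barcode", "in_tissue", "array_row", "array_col",
                 "pxl_row_in_fullres", "pxl_col_in_fullres")
  if (!all(need_cols %in% names(pos))) {
    stop("tissue_positions.csv must have header columns: ",
         paste(need_cols, collapse = ", "))
  }
  extra <- setdiff(pos$barcode, barcodes)
  missing <- setdiff(barcodes, pos$barcode)
  if (length(missing) > 0L) {
    stop(sprintf(paste0("%d matrix barcode(s) absent from ",
                        "tissue_positions.csv (e.g. %s)"),
                 length(missing), missing[1L]))
  }
  if (length(extra) > 0L) {
    ## positions may list non-matrix barcodes (e.g. out-of-tissue spots in a
    ## filtered matrix); they are ignored
    pos <- pos[pos$barcode %in% barcodes, , drop = FALSE]
  }
  pos <- pos[match(barcodes, pos$barcode), , drop = FALSE]

  sf <- jsonlite::read_json(f_sf, simplifyVector = TRUE)
  if (is.null(sf$spot_diameter_fullres) || is.null(sf$tissue_lowres_scalef)) {
    stop("scalefactors_json.json must contain spot_diameter_fullres ",
         "and tissue_lowres_scalef")
  }
  lowres <- read_pixels(f_img)
  scalef <- sf$tissue_lowres_scalef
  full_w <- dim(lowres)[2L] / scalef
  full_h <- dim(lowres)[1L] / scalef

  x <- pos$pxl_col_in_fullres
  y <- if (y_convention == "up") full_h - pos$pxl_row_in_fullres
       else pos$pxl_row_in_fullres
  col_meta <- data.frame(barcode = barcodes, sample_id = "sample01",
                         in_tissue = pos$in_tissue,
                         array_row = pos$array_row,
                         array_col = pos$array_col)
  row_meta <- feats
  sfc <- new_container(counts, col_meta, row_meta, units = "full_res_pixel")
  cent <- geometry_layer(lapply(seq_along(x), function(i) gf_point(x[i], y[i])),
                         "POINT", data.frame(barcode = barcodes))
  sfc <- set_geometry(sfc, "col", "centroids", cent)
  r <- sf$spot_diameter_fullres / 2
  spots <- geometry_layer(lapply(seq_along(x), function(i)
    gf_regular_polygon(c(x[i], y[i]), r, 32L)),
    "POLYGON", data.frame(barcode = barcodes))
  sfc <- set_geometry(sfc, "col", "spotPoly", spots)
  img_ext <- if (y_convention == "up") spatial_extent(0, 0, full_w, full_h)
             else spatial_extent(0, 0, full_w, full_h)
  img <- memory_image(if (y_convention == "up") lowres else px_mirror_v(lowres),
                      img_ext)
  sfc <- set_image(sfc, "lowres", img)
  sfc@metadata$scalefactors <- sf
  sfc
}
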