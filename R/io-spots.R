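#' Read a transcript-spot table into per-gene multipoints
#'
#' Reads a CSV of transcript spot coordinates (one row per detected
#' transcript), groups the spots by gene into MULTIPOINT geometries (spot
#' order preserved within each gene, genes in order of first appearance), and
#' writes the result to a GeoParquet cache for faster future reads. When the
#' cache already exists and is newer than the source CSV, it is read instead
#' of the CSV (with a message).
#'
#' @param path CSV file with at least x, y, and gene columns.
#' @param x_col,y_col,gene_col column names (defaults `"x"`, `"y"`,
#'   `"gene"`).
#' @param cache GeoParquet cache path (default `<path>.parquet`); `NULL`
#'   disables caching.
#' @return a MULTIPOINT [GeometryLayer-class] with a `gene` attribute column
#'   (one multipoint per gene).
#' @export
read_transcript_spots <- function(path, x_col = "x", y_col = "y",
                                  gene_col = "gene",
                                  cache = paste0(path, ".parquet")) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!is.null(cache) && file.exists(cache) &&
      file.mtime(cache) >= file.mtime(path)) {
    message("reading cached GeoParquet: ", cache)
    return(read_geoparquet(cache))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c(x_col, y_col, gene_col)) {
    if (!col %in% names(df)) stop("column '", col, "' not found in ", path)
  }
  suppress_to_na <- function(v) suppressWarnings(as.numeric(v))
  x <- suppress_to_na(df[[x_col]])
  y <- suppress_to_na(df[[y_col]])
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad) > 0L) {
    stop(sprintf("non-numeric coordinates at row %d of %s", bad[1L], path))
  }
  genes <- as.character(df[[gene_col]])
  ugenes <- unique(genes)
  geoms <- lapply(ugenes, function(g) {
    idx <- which(genes == g)
    gf_multipoint(cbind(x[idx], y[idx]))
  })
  layer <- geometry_layer(geoms, "MULTIPOINT", data.frame(gene = ugenes))
  if (!is.null(cache)) write_geoparquet(layer, cache)
  layer
}

#' Attach per-gene transcript multipoints as a row geometry
#'
#' Aligns a MULTIPOINT layer (one geometry per gene, `gene` attribute) to the
#' container's features; genes with no spots get empty multipoints.
#'
#' @param c a [SpatialFeatureContainer-class].
#' @param spots a MULTIPOINT [GeometryLayer-class] with a `gene` column.
#' @param name row geometry name (default `"txSpots"`).
#' @param feature_col `row_meta` column holding feature ids (default the
#'   first column).
#' @export
set_transcript_spots <- function(c, spots, name = "txSpots",
                                 feature_col = NULL) {
  if (is.null(feature_col)) feature_col <- names(c@row_meta)[1L]
  feats <- as.character(c@row_meta[[feature_col]])
  idx <- match(feats, as.character(spots@attrs$gene))
  geoms <- lapply(idx, function(i) {
    if (is.na(i)) gf_multipoint(matrix(numeric(0), ncol = 2L))
    else spots@geoms[[i]]
  })
  layer <- geometry_layer(geoms, "MULTIPOINT", data.frame(gene = feats))
  set_geometry(c, "row", name, layer)
}
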