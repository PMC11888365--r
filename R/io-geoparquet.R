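wkb_type_name <- function(type) {
  c(POINT = "Point", MULTIPOINT = "MultiPoint", LINESTRING = "LineString",
    POLYGON = "Polygon", MULTIPOLYGON = "MultiPolygon")[[type]]
}

#' Write a geometry layer as GeoParquet
#'
#' Standard GeoParquet: attribute columns plus a `geometry` column of
#' well-known-binary blobs, with the `geo` file metadata (version, primary
#' column, geometry types, bbox). Coordinates survive a round trip
#' bit-exactly (WKB stores raw doubles).
#'
#' @param layer a [GeometryLayer-class] (homogeneous geometry type).
#' @param path output `.parquet` path.
#' @export
write_geoparquet <- function(layer, path) {
  stopifnot(is(layer, "GeometryLayer"))
  wkb <- lapply(layer@geoms, geom_to_wkb, type = layer@geom_type)
  attrs <- layer@attrs
  cols <- c(as.list(attrs), list(geometry = arrow::Array$create(
    wkb, type = arrow::binary())))
  tab <- do.call(arrow::arrow_table, cols)
  geo_col <- list(encoding = "WKB",
                  geometry_types = list(wkb_type_name(layer@geom_type)))
  if (n_geometries(layer) > 0L) {
    co <- do.call(rbind, lapply(layer@geoms, geom_coords,
                                type = layer@geom_type))
    if (!is.null(co) && nrow(co) > 0L) {
      geo_col$bbox <- c(min(co[, 1L]), min(co[, 2L]),
                        max(co[, 1L]), max(co[, 2L]))
    }
  }
  tab$metadata[["geo"]] <- jsonlite::toJSON(
    list(version = "1.1.0", primary_column = "geometry",
         columns = list(geometry = geo_col),
         geom_type = layer@geom_type),
    auto_unbox = TRUE, digits = NA)
  arrow::write_parquet(tab, path)
  invisible(path)
}

#' Read a GeoParquet file into a geometry layer
#'
#' @param path a `.parquet` file with `geo` metadata and a WKB geometry
#'   column.
#' @return a [GeometryLayer-class].
#' @export
read_geoparquet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- arrow::read_parquet(path, as_data_frame = FALSE)
  meta <- tab$metadata[["geo"]]
  if (is.null(meta)) {
    stop("'", path, "' is not a GeoParquet file (no 'geo' metadata)")
  }
  geo <- jsonlite::fromJSON(meta)
  gcol <- geo$primary_column %||% "geometry"
  if (!gcol %in% names(tab)) {
    stop("GeoParquet metadata names geometry column '", gcol,
         "' which is absent from the file")
  }
  wkb <- as.vector(tab[[gcol]])
  df <- as.data.frame(tab)
  df[[gcol]] <- NULL
  if (length(wkb) == 0L) {
    type <- geo$geom_type %||% "POINT"
    return(geometry_layer(list(), type, df[0, , drop = FALSE]))
  }
  decoded <- lapply(wkb, wkb_to_geom)
  types <- unique(vapply(decoded, `[[`, "", "type"))
  if (length(types) != 1L) {
    stop("mixed geometry types in GeoParquet file: ",
         paste(types, collapse = ", "))
  }
  geometry_layer(lapply(decoded, `[[`, "geom"), types, df)
}
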