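CONTAINER_FORMAT_VERSION <- "1.0"

#' Save a container to a language-agnostic on-disk layout
#'
#' Directory layout:
#' \preformatted{
#'   manifest.json                       format version, units, inventory,
#'                                       image extents
#'   assays/<name>.mtx                   MatrixMarket (full precision)
#'   row_meta.csv, col_meta.csv
#'   geometries/{col|row|annot}/<name>.parquet   GeoParquet
#'   graphs/{col|annot}/<name>.json      0-based edge lists
#'   local_results/<statistic>/<feature>.csv
#'   images/<name>.tiff                  16-bit lossless TIFF
#' }
#' Assays, geometry coordinates, and graphs round-trip exactly; images
#' round-trip bit-exactly when pixel values lie on the 16-bit grid
#' (`k / 65535`, which includes everything read from 8- or 16-bit files);
#' metadata tables round-trip up to CSV column-type rules (numeric, integer,
#' logical, and character columns are restored; everything else becomes
#' character), which are stated in the manifest.
#'
#' @param c a [SpatialFeatureContainer-class].
#' @param dir output directory (created; must not already contain a
#'   manifest).
#' @export
save_container <- function(c, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "assays"), showWarnings = FALSE)
  manifest <- list(
    format_version = CONTAINER_FORMAT_VERSION,
    units = c@units,
    n_features = n_features(c),
    n_locations = n_locations(c),
    column_type_rules = "numeric/integer/logical/character preserved; others read back as character",
    assays = as.list(names(c@assays))
  )
  dn <- dimnames(c@assays[[1L]])
  if (!is.null(dn)) {
    manifest$assay_dimnames <- list(rows = dn[[1L]], cols = dn[[2L]])
  }
  for (nm in names(c@assays)) {
    Matrix::writeMM(methods::as(Matrix::Matrix(c@assays[[nm]], sparse = TRUE),
                                "generalMatrix"),
                    file.path(dir, "assays", paste0(nm, ".mtx")))
  }
  utils::write.csv(c@row_meta, file.path(dir, "row_meta.csv"),
                   row.names = FALSE)
  utils::write.csv(c@col_meta, file.path(dir, "col_meta.csv"),
                   row.names = FALSE)
  geom_inv <- list()
  for (axis in c("col", "row", "annot")) {
    layers <- slot(c, geom_slot(axis))
    if (length(layers) == 0L) next
    adir <- file.path(dir, "geometries", axis)
    dir.create(adir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(layers)) {
      write_geoparquet(layers[[nm]], file.path(adir, paste0(nm, ".parquet")))
    }
    geom_inv[[axis]] <- as.list(names(layers))
  }
  if (length(geom_inv)) manifest$geometries <- geom_inv
  graph_inv <- list()
  for (scope in c("col", "annot")) {
    gs <- slot(c, graph_slot(scope))
    if (length(gs) == 0L) next
    gdir <- file.path(dir, "graphs", scope)
    dir.create(gdir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(gs)) {
      write_graph_json(gs[[nm]], file.path(gdir, paste0(nm, ".json")))
    }
    graph_inv[[scope]] <- as.list(names(gs))
  }
  if (length(graph_inv)) manifest$graphs <- graph_inv
  if (length(c@local_results)) {
    lr_inv <- list()
    for (st in names(c@local_results)) {
      sdir <- file.path(dir, "local_results", st)
      dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
      for (ft in names(c@local_results[[st]])) {
        write_numeric_csv(c@local_results[[st]][[ft]],
                          file.path(sdir, paste0(ft, ".csv")))
      }
      lr_inv[[st]] <- as.list(names(c@local_results[[st]]))
    }
    manifest$local_results <- lr_inv
  }
  if (length(c@images)) {
    dir.create(file.path(dir, "images"), showWarnings = FALSE)
    manifest$images <- lapply(names(c@images), function(nm) {
      img <- c@images[[nm]]
      write_image(img, file.path(dir, "images", paste0(nm, ".tiff")))
      e <- as_extent_vec(img_extent(img))
      list(name = nm, extent = list(xmin = e[1], ymin = e[2],
                                    xmax = e[3], ymax = e[4]))
    })
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

## numeric matrix -> CSV at full double precision (%.17g survives the
## decimal round trip exactly)
write_numeric_csv <- function(m, path) {
  m <- as.matrix(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  lines <- c(paste(colnames(m), collapse = ","),
             apply(matrix(sprintf("%.17g", m), nrow(m)), 1L, paste,
                   collapse = ","))
  if (nrow(m) == 0L) lines <- lines[1L]
  writeLines(lines, path)
  invisible(path)
}

write_graph_json <- function(g, path) {
  e <- g@edges
  edges <- lapply(seq_len(nrow(e)), function(r)
    list(e$i[r] - 1L, e$j[r] - 1L, e$weight[r]))  # 0-based interchange
  mm <- g@method_meta
  jsonlite::write_json(
    list(n_nodes = g@n_nodes, edges = edges, style = g@style,
         directed = g@directed, method_meta = mm),
    path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

read_graph_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  ne <- length(j$edges)
  e <- data.frame(
    i = vapply(j$edges, function(x) as.integer(x[[1L]]), 0L) + 1L,
    j = vapply(j$edges, function(x) as.integer(x[[2L]]), 0L) + 1L,
    weight = vapply(j$edges, function(x) as.numeric(x[[3L]]), 0))
  mm <- j$method_meta
  mm$params <- lapply(mm$params, function(p) {
    if (is.list(p)) p <- unlist(p)
    if (is.integer(p)) p <- as.numeric(p)  # JSON does not keep int/dbl apart
    p
  })
  mm$layer <- if (is.null(mm$layer)) NA_character_ else mm$layer
  mm$method <- if (is.null(mm$method)) NA_character_ else mm$method
  mm$subsetted <- isTRUE(mm$subsetted)
  if (!is.null(mm$distances)) mm$distances <- as.numeric(unlist(mm$distances))
  new("SpatialGraph", n_nodes = as.integer(j$n_nodes), edges = e,
      style = j$style, directed = isTRUE(j$directed), method_meta = mm)
}

require_file <- function(path) {
  if (!file.exists(path)) {
    stop("manifest declares '", path, "' but the file is missing")
  }
  path
}

#' Load a container saved with [save_container()]
#'
#' @param dir directory containing `manifest.json`.
#' @return a [SpatialFeatureContainer-class].
#' @export
load_container <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(manifest$format_version, CONTAINER_FORMAT_VERSION)) {
    stop(sprintf("on-disk format version '%s' does not match this package's version '%s'",
                 manifest$format_version, CONTAINER_FORMAT_VERSION))
  }
  read_meta <- function(path, n) {
    if (n == 0L) {
      hdr <- utils::read.csv(path, nrows = 1L)
      return(hdr[0, , drop = FALSE])
    }
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  assay_names <- unlist(manifest$assays)
  assays <- list()
  for (nm in assay_names) {
    a <- as.matrix(Matrix::readMM(
      require_file(file.path(dir, "assays", paste0(nm, ".mtx")))))
    if (!is.null(manifest$assay_dimnames)) {
      dimnames(a) <- list(manifest$assay_dimnames$rows,
                          manifest$assay_dimnames$cols)
    }
    assays[[nm]] <- a
  }
  row_meta <- read_meta(require_file(file.path(dir, "row_meta.csv")),
                        manifest$n_features)
  col_meta <- read_meta(require_file(file.path(dir, "col_meta.csv")),
                        manifest$n_locations)
  c <- new_container(assays[[1L]], col_meta, row_meta, units = manifest$units)
  c@assays <- assays
  for (axis in names(manifest$geometries)) {
    for (nm in unlist(manifest$geometries[[axis]])) {
      layer <- read_geoparquet(require_file(
        file.path(dir, "geometries", axis, paste0(nm, ".parquet"))))
      c <- set_geometry(c, axis, nm, layer)
    }
  }
  for (scope in names(manifest$graphs)) {
    for (nm in unlist(manifest$graphs[[scope]])) {
      g <- read_graph_json(require_file(
        file.path(dir, "graphs", scope, paste0(nm, ".json"))))
      c <- set_graph(c, scope, nm, g)
    }
  }
  for (st in names(manifest$local_results)) {
    for (ft in unlist(manifest$local_results[[st]])) {
      m <- as.matrix(utils::read.csv(require_file(
        file.path(dir, "local_results", st, paste0(ft, ".csv")))))
      c <- set_local_result(c, st, ft, m)
    }
  }
  if (!is.null(manifest$images)) {
    imgs <- manifest$images
    for (k in seq_len(nrow(imgs))) {
      ext <- imgs$extent[k, ]
      img <- load_image(require_file(
        file.path(dir, "images", paste0(imgs$name[k], ".tiff"))),
        extent = spatial_extent(ext$xmin, ext$ymin, ext$xmax, ext$ymax))
      c <- set_image(c, imgs$name[k], img)
    }
  }
  c
}
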