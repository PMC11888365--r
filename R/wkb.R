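## Well-known-binary (WKB) encoding of the package's geometry structures.
## Little-endian, 2-D, standard type codes: 1 point, 2 linestring, 3 polygon,
## 4 multipoint, 6 multipolygon.

wkb_uint32 <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                                   endian = "little")
wkb_doubles <- function(x) writeBin(as.numeric(x), raw(), size = 8L,
                                    endian = "little")

wkb_header <- function(code) c(as.raw(1L), wkb_uint32(code))

wkb_coords <- function(m) wkb_doubles(as.numeric(t(m)))

#' Encode a geometry as WKB
#' @param geom geometry structure (see [geometry-primitives]).
#' @param type its geometry type.
#' @return a raw vector.
#' @export
geom_to_wkb <- function(geom, type) {
  switch(type,
    POINT = c(wkb_header(1L), wkb_doubles(geom)),
    LINESTRING = c(wkb_header(2L), wkb_uint32(nrow(geom)), wkb_coords(geom)),
    POLYGON = c(wkb_header(3L), wkb_uint32(length(geom)),
                unlist(lapply(geom, function(r)
                  c(wkb_uint32(nrow(r)), wkb_coords(r))))),
    MULTIPOINT = c(wkb_header(4L), wkb_uint32(nrow(geom)),
                   unlist(lapply(seq_len(nrow(geom)), function(i)
                     geom_to_wkb(geom[i, ], "POINT")))),
    MULTIPOLYGON = c(wkb_header(6L), wkb_uint32(length(geom)),
                     unlist(lapply(geom, geom_to_wkb, type = "POLYGON"))),
    stop("cannot WKB-encode type ", type)
  )
}

## stateful raw-vector reader
wkb_reader <- function(raw_vec) {
  pos <- 0L
  list(
    u32 = function() {
      v <- readBin(raw_vec[(pos + 1L):(pos + 4L)], "integer", size = 4L,
                   endian = "little")
      pos <<- pos + 4L
      v
    },
    dbl = function(n) {
      v <- readBin(raw_vec[(pos + 1L):(pos + 8L * n)], "numeric", n = n,
                   size = 8L, endian = "little")
      pos <<- pos + 8L * n
      v
    },
    byte = function() {
      v <- as.integer(raw_vec[pos + 1L])
      pos <<- pos + 1L
      v
    }
  )
}

wkb_read_geom <- function(rd) {
  endian <- rd$byte()
  if (endian != 1L) stop("only little-endian WKB is supported")
  code <- rd$u32()
  if (code == 1L) {
    return(list(geom = rd$dbl(2L), type = "POINT"))
  }
  if (code == 2L) {
    n <- rd$u32()
    return(list(geom = matrix(rd$dbl(2L * n), ncol = 2L, byrow = TRUE),
                type = "LINESTRING"))
  }
  if (code == 3L) {
    nr <- rd$u32()
    rings <- lapply(seq_len(nr), function(i) {
      n <- rd$u32()
      matrix(rd$dbl(2L * n), ncol = 2L, byrow = TRUE)
    })
    return(list(geom = rings, type = "POLYGON"))
  }
  if (code == 4L) {
    n <- rd$u32()
    pts <- t(vapply(seq_len(n), function(i) wkb_read_geom(rd)$geom,
                    numeric(2)))
    if (n == 0L) pts <- matrix(numeric(0), ncol = 2L)
    return(list(geom = pts, type = "MULTIPOINT"))
  }
  if (code == 6L) {
    n <- rd$u32()
    polys <- lapply(seq_len(n), function(i) wkb_read_geom(rd)$geom)
    return(list(geom = polys, type = "MULTIPOLYGON"))
  }
  stop("unsupported WKB geometry type code: ", code)
}

#' Decode a WKB raw vector
#' @param raw_vec a raw vector of WKB bytes.
#' @return list with `geom` and `type`.
#' @export
wkb_to_geom <- function(raw_vec) wkb_read_geom(wkb_reader(raw_vec))
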