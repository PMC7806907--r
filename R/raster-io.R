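#' Read a georeferenced raster (TIFF + world file)
#'
#' Rasters are stored as TIFF images accompanied by an ESRI world file
#' (`.tfw`) holding the affine geotransform and a small JSON sidecar
#' (`<path>.aux.json`) holding band names, nodata and the on-disk encoding.
#' Two encodings are used: `uint8` (byte imagery such as RGB orthomosaics,
#' stored bit-exactly) and `float` (continuous layers such as DSMs, stored
#' as affinely packed 32-bit samples whose packing range is recorded in the
#' sidecar). A TIFF without a world file is rejected as ungeoreferenced.
#'
#' @param path path to a `.tif` file written by [write_raster()] (or any
#'   TIFF with a matching world file).
#' @return a [raster_grid].
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  wf <- world_file_path(path)
  if (!file.exists(wf)) {
    stop("unreadable or ungeoreferenced raster: missing world file ", wf)
  }
  tf <- tryCatch(tiff::readTIFF(path), error = function(e) {
    stop("unreadable or ungeoreferenced raster: ", conditionMessage(e))
  })
  if (is.matrix(tf)) tf <- array(tf, c(dim(tf), 1L))
  w <- as.numeric(readLines(wf, n = 6L))
  cell <- w[1]
  if (!isTRUE(all.equal(cell, -w[4])) || w[2] != 0 || w[3] != 0) {
    stop("only square north-up pixels are supported")
  }
  # world file stores the centre of the top-left pixel
  origin <- c(w[5] - cell / 2, w[6] + cell / 2)
  aux_path <- paste0(path, ".aux.json")
  aux <- if (file.exists(aux_path)) jsonlite::read_json(aux_path) else list()
  nodata <- if (is.null(aux$nodata)) NA_real_ else as.numeric(aux$nodata)
  band_names <- if (is.null(aux$band_names)) NULL else
    unlist(aux$band_names, use.names = FALSE)
  enc <- if (is.null(aux$encoding)) "float01" else aux$encoding
  vals <- switch(enc,
    uint8 = round(tf * 255),
    float = {
      lo <- as.numeric(aux$pack_min); hi <- as.numeric(aux$pack_max)
      if (hi > lo) tf * (hi - lo) + lo else tf * 0 + lo
    },
    float01 = tf,
    stop("unknown raster encoding: ", enc)
  )
  if (!is.na(nodata)) vals[abs(vals - nodata) < 1e-6 * max(1, abs(nodata))] <- NA
  raster_grid(vals, origin = origin, cell_size = cell, nodata = nodata,
              band_names = band_names)
}

#' Write a georeferenced raster (TIFF + world file)
#'
#' Byte imagery (all values integers in 0..255 and no nodata, or
#' `encoding = "uint8"`) is stored bit-exactly as 8-bit samples. Other
#' rasters are affinely packed into 32-bit samples; values then round-trip
#' at single precision (about 7 significant digits of the band range).
#'
#' @param grid a [raster_grid].
#' @param path output `.tif` path; the `.tfw` world file and `.aux.json`
#'   sidecar are written next to it.
#' @param encoding `"auto"`, `"uint8"` or `"float"`.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, encoding = c("auto", "uint8", "float")) {
  stopifnot(inherits(grid, "raster_grid"))
  encoding <- match.arg(encoding)
  v <- grid$values
  if (anyNA(v)) {
    if (is.na(grid$nodata)) {
      stop("raster has NA cells but no nodata sentinel; set `nodata`")
    }
    v[is.na(v)] <- grid$nodata
  }
  if (encoding == "auto") {
    is_byte <- all(v >= 0 & v <= 255 & v == round(v))
    encoding <- if (is_byte) "uint8" else "float"
  }
  aux <- list(band_names = grid$band_names, encoding = encoding)
  if (!is.na(grid$nodata)) aux$nodata <- grid$nodata
  if (encoding == "uint8") {
    if (any(v < 0 | v > 255 | v != round(v))) {
      stop("uint8 encoding requires integer values in [0, 255]")
    }
    img <- v / 255
    bits <- 8L
  } else {
    lo <- min(v); hi <- max(v)
    aux$pack_min <- lo; aux$pack_max <- hi
    img <- if (hi > lo) (v - lo) / (hi - lo) else v * 0
    bits <- 32L
  }
  if (dim(img)[3] == 1L) img <- img[, , 1]
  tiff::writeTIFF(img, path, bits.per.sample = bits, compression = "none",
                  reduce = FALSE)
  cell <- grid$cell_size
  writeLines(format(c(cell, 0, 0, -cell,
                      grid$origin[1] + cell / 2, grid$origin[2] - cell / 2),
                    digits = 17),
             world_file_path(path))
  jsonlite::write_json(aux, paste0(path, ".aux.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

world_file_path <- function(path) {
  sub("\\.[^.]+$", ".tfw", path)
}

#' Write polygons to GeoJSON
#'
#' @param features list of features, each a list with fields `polygon`
#'   (either a two-column coordinate matrix for a simple ring, or a list
#'   with `outer` and `holes` rings) and any scalar properties (e.g. `id`,
#'   `class`).
#' @param path output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(features, path) {
  fjson <- lapply(features, function(f) {
    rings <- polygon_rings(f$polygon)
    coords <- lapply(rings, function(r) {
      r <- close_ring(r)
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
    })
    props <- f[setdiff(names(f), "polygon")]
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = coords),
         properties = props)
  })
  obj <- list(type = "FeatureCollection", features = fjson)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read polygons from GeoJSON
#'
#' @param path a `.geojson` file with Polygon features.
#' @return list of features with `polygon` (ring matrix, or `outer`/`holes`
#'   list when holes are present) plus all scalar properties.
#' @export
read_geojson <- function(path) {
  if (!file.exists(path)) stop("GeoJSON file not found: ", path)
  obj <- jsonlite::read_json(path)
  if (!identical(obj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection")
  }
  lapply(obj$features, function(ft) {
    if (!identical(ft$geometry$type, "Polygon")) {
      stop("only Polygon geometries are supported, got: ", ft$geometry$type)
    }
    rings <- lapply(ft$geometry$coordinates, function(ring) {
      m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
      open_ring(m)
    })
    poly <- if (length(rings) == 1L) rings[[1]] else
      list(outer = rings[[1]], holes = rings[-1])
    c(list(polygon = poly), ft$properties)
  })
}

# --- small polygon helpers shared across modules ------------------------

polygon_rings <- function(poly) {
  if (is.matrix(poly)) list(poly) else c(list(poly$outer), poly$holes)
}

close_ring <- function(r) {
  if (!all(r[1, ] == r[nrow(r), ])) r <- rbind(r, r[1, ])
  r
}

open_ring <- function(r) {
  if (nrow(r) > 1L && all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
  r
}

# signed shoelace area of an open ring
ring_area_signed <- function(r) {
  x <- r[, 1]; y <- r[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

#' Polygon area (outer ring minus holes)
#'
#' @param poly ring matrix or `outer`/`holes` list.
#' @return nonnegative area in the polygon's coordinate units.
#' @export
polygon_area <- function(poly) {
  rings <- polygon_rings(poly)
  a <- abs(ring_area_signed(rings[[1]]))
  if (length(rings) > 1L) {
    a <- a - sum(vapply(rings[-1], function(r) abs(ring_area_signed(r)), 0))
  }
  a
}

polygon_centroid <- function(poly) {
  rings <- polygon_rings(poly)
  cw <- function(r, sgn) {
    x <- r[, 1]; y <- r[, 2]
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    cr <- x * yn - xn * y
    a <- sum(cr) / 2
    if (a == 0) return(c(0, 0, 0))
    c(sum((x + xn) * cr) / 6, sum((y + yn) * cr) / 6, a) * sgn
  }
  acc <- cw(rings[[1]], 1)
  sgn0 <- sign(ring_area_signed(rings[[1]]))
  if (length(rings) > 1L) {
    for (h in rings[-1]) {
      sh <- sign(ring_area_signed(h))
      # holes subtract regardless of stored orientation
      acc <- acc + cw(h, if (sh == sgn0) -1 else 1)
    }
  }
  c(acc[1] / acc[3], acc[2] / acc[3])
}
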