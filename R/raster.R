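#' Aligned multi-band raster grid
#'
#' `raster_grid` is the common currency of all raster stages: a stack of one
#' or more co-registered bands with a geotransform (map origin and square
#' cell size in metres) and an optional nodata sentinel. Nodata cells are
#' represented as `NA` in memory and never enter band statistics.
#'
#' The geotransform follows the usual north-up affine convention: `origin`
#' is the map coordinate of the top-left corner of the top-left pixel, x
#' increases with column index, y decreases with row index, and both pixel
#' dimensions equal `cell_size`.
#'
#' @param values numeric matrix (rows x cols) or 3-d array
#'   (rows x cols x bands).
#' @param origin length-2 numeric, map (x, y) of the top-left raster corner.
#' @param cell_size positive pixel size in metres.
#' @param nodata sentinel used on disk for missing cells (`NA` cells in
#'   memory); `NA` means the raster has no nodata concept.
#' @param band_names character vector, one name per band.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, origin = c(0, 0), cell_size = 1,
                        nodata = NA_real_, band_names = NULL) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a matrix or a rows x cols x bands array")
  }
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("`cell_size` must be a single positive number")
  }
  nb <- dim(values)[3]
  if (is.null(band_names)) band_names <- paste0("band", seq_len(nb))
  if (length(band_names) != nb) stop("one band name per band required")
  structure(
    list(values = values, origin = as.numeric(origin[1:2]),
         cell_size = as.numeric(cell_size), nodata = nodata,
         band_names = as.character(band_names)),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<raster_grid> %d x %d px, %d band(s) [%s]\n", d[1], d[2], d[3],
              paste(x$band_names, collapse = ", ")))
  cat(sprintf("  origin (%.3f, %.3f), cell %.4g m, nodata %s\n",
              x$origin[1], x$origin[2], x$cell_size, format(x$nodata)))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

n_bands <- function(grid) dim(grid$values)[3]

#' Elevation surface (DSM)
#'
#' A single-band digital surface model: canopy-top elevation in metres on a
#' square grid.
#'
#' @param elevation numeric matrix of elevations (metres); `NA` = nodata.
#' @param cell_size positive pixel size in metres.
#' @param origin map coordinate of the top-left raster corner.
#' @return an object of class `surface_model`.
#' @export
surface_model <- function(elevation, cell_size, origin = c(0, 0)) {
  if (!is.matrix(elevation)) stop("`elevation` must be a matrix")
  if (cell_size <= 0) stop("`cell_size` must be positive")
  structure(list(elevation = elevation, cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin[1:2])),
            class = "surface_model")
}

#' @export
print.surface_model <- function(x, ...) {
  cat(sprintf("<surface_model> %d x %d px, cell %.4g m\n",
              nrow(x$elevation), ncol(x$elevation), x$cell_size))
  invisible(x)
}

#' Terrain slope model derived from a DSM
#'
#' Per-cell maximum rate of elevation change, in degrees; used to emphasise
#' crown borders before segmentation.
#'
#' @param slope numeric matrix of slope angles in degrees, in `[0, 90)`.
#' @param cell_size positive pixel size in metres.
#' @param origin map coordinate of the top-left raster corner.
#' @return an object of class `slope_model`.
#' @export
slope_model <- function(slope, cell_size, origin = c(0, 0)) {
  structure(list(slope = slope, cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin[1:2])),
            class = "slope_model")
}

#' Compute terrain slope from a DSM (Horn's method)
#'
#' Slope is the maximum rate of elevation change between each cell and its
#' neighbours, computed from Horn's 3x3 weighted finite differences — the
#' default of standard GIS slope tools:
#' \deqn{g_x = \frac{(c + 2f + i) - (a + 2d + g)}{8\,\Delta},\quad
#'       g_y = \frac{(g + 2h + i) - (a + 2b + c)}{8\,\Delta}}
#' over the 3x3 window `a b c / d e f / g h i`, with the slope angle
#' `atan(sqrt(gx^2 + gy^2))` converted to degrees. Edge cells use a
#' clamp-to-edge (replicated border) neighbourhood so the output grid keeps
#' the input footprint.
#'
#' @param dsm a [surface_model].
#' @return a [slope_model] with slope in degrees, `NA` wherever any cell of
#'   the 3x3 neighbourhood is nodata.
#' @export
compute_slope <- function(dsm) {
  stopifnot(inherits(dsm, "surface_model"))
  z <- dsm$elevation
  if (nrow(z) < 3L || ncol(z) < 3L) {
    stop("DSM must be at least 3 x 3 cells to derive slope")
  }
  if (all(is.na(z))) stop("DSM contains no valid elevation")
  nr <- nrow(z); nc <- ncol(z)
  ri <- c(1L, seq_len(nr), nr)   # clamp-to-edge padding indices
  ci <- c(1L, seq_len(nc), nc)
  zp <- z[ri, ci]
  up <- seq_len(nr); mid <- up + 1L; dn <- up + 2L
  lf <- seq_len(nc); cm <- lf + 1L; rt <- lf + 2L
  a <- zp[up, lf]; b <- zp[up, cm]; cc <- zp[up, rt]
  d <- zp[mid, lf];                 f <- zp[mid, rt]
  g <- zp[dn, lf]; h <- zp[dn, cm]; i <- zp[dn, rt]
  gx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * dsm$cell_size)
  gy <- ((g + 2 * h + i) - (a + 2 * b + cc)) / (8 * dsm$cell_size)
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  slope_model(slope, dsm$cell_size, dsm$origin)
}

#' Bilinear resampling of a matrix or band array
#'
#' Pixel-centre registration: output centre `(i, j)` maps to input
#' coordinate `((i - 0.5) * nrow_in / nrow_out + 0.5, ...)`, clamped to the
#' input domain.
#'
#' @param values matrix or rows x cols x bands array.
#' @param out_nrow,out_ncol output grid dimensions.
#' @return resampled matrix/array of the requested size.
#' @export
resample_bilinear <- function(values, out_nrow, out_ncol) {
  was_mat <- is.matrix(values)
  if (was_mat) values <- array(values, c(dim(values), 1L))
  nr <- dim(values)[1]; nc <- dim(values)[2]; nb <- dim(values)[3]
  rr <- pmin(pmax((seq_len(out_nrow) - 0.5) * nr / out_nrow + 0.5, 1), nr)
  ccv <- pmin(pmax((seq_len(out_ncol) - 0.5) * nc / out_ncol + 0.5, 1), nc)
  r0 <- pmin(floor(rr), nr - 1L); r1 <- r0 + 1L; fr <- rr - r0
  c0 <- pmin(floor(ccv), nc - 1L); c1 <- c0 + 1L; fc <- ccv - c0
  if (nr == 1L) { r0 <- r1 <- rep(1L, out_nrow); fr <- rep(0, out_nrow) }
  if (nc == 1L) { c0 <- c1 <- rep(1L, out_ncol); fc <- rep(0, out_ncol) }
  out <- array(NA_real_, c(out_nrow, out_ncol, nb))
  FR <- matrix(fr, out_nrow, out_ncol)
  FC <- matrix(fc, out_nrow, out_ncol, byrow = TRUE)
  for (b in seq_len(nb)) {
    v <- values[, , b]
    v00 <- v[r0, c0, drop = FALSE]; v01 <- v[r0, c1, drop = FALSE]
    v10 <- v[r1, c0, drop = FALSE]; v11 <- v[r1, c1, drop = FALSE]
    out[, , b] <- (1 - FR) * ((1 - FC) * v00 + FC * v01) +
      FR * ((1 - FC) * v10 + FC * v11)
  }
  if (was_mat) out[, , 1] else out
}

#' Build the 5-band segmentation layer stack
#'
#' Stacks the RGB orthomosaic, the DSM and the slope model into one
#' co-registered multi-band grid (bands `R, G, B, DSM, slope`). DSM-resolution
#' layers are bilinearly resampled to the orthomosaic grid first. The layer
#' weights are carried with the stack and consumed by the segmentation merge
#' criterion; a zero weight removes that layer's influence entirely.
#'
#' @param ortho 3-band [raster_grid] (R, G, B).
#' @param dsm a [surface_model], same footprint (possibly coarser GSD).
#' @param slope a [slope_model], same footprint as the DSM.
#' @param weights numeric length 5, nonnegative per-layer weights.
#' @return a 5-band [raster_grid] with a `layer_weights` field.
#' @export
stack_layers <- function(ortho, dsm, slope, weights = rep(1, 5)) {
  stopifnot(inherits(ortho, "raster_grid"), inherits(dsm, "surface_model"),
            inherits(slope, "slope_model"))
  if (n_bands(ortho) != 3L) stop("orthomosaic must have 3 bands (R, G, B)")
  if (length(weights) != 5L || any(weights < 0)) {
    stop("`weights` must be 5 nonnegative numbers (R, G, B, DSM, slope)")
  }
  d <- dim(ortho$values)
  # footprints must agree before resampling to the ortho grid
  ext_ok <- function(cs, n_px, n_ref) {
    isTRUE(all.equal(cs * n_px, ortho$cell_size * n_ref, tolerance = 1e-6))
  }
  if (!isTRUE(all.equal(dsm$origin, ortho$origin, tolerance = 1e-6)) ||
      !ext_ok(dsm$cell_size, nrow(dsm$elevation), d[1]) ||
      !ext_ok(dsm$cell_size, ncol(dsm$elevation), d[2])) {
    stop("DSM geotransform does not match the orthomosaic footprint")
  }
  zd <- resample_bilinear(dsm$elevation, d[1], d[2])
  zs <- resample_bilinear(slope$slope, d[1], d[2])
  vals <- array(NA_real_, c(d[1], d[2], 5L))
  vals[, , 1:3] <- ortho$values
  vals[, , 4] <- zd
  vals[, , 5] <- zs
  g <- raster_grid(vals, ortho$origin, ortho$cell_size, ortho$nodata,
                   c("R", "G", "B", "DSM", "slope"))
  g$layer_weights <- as.numeric(weights)
  g
}

#' Per-band summary statistics excluding nodata
#'
#' @param grid a [raster_grid].
#' @return tibble with one row per band: mean, population SD, min, max, and
#'   the count of valid (non-nodata) cells.
#' @export
band_stats <- function(grid) {
  stopifnot(inherits(grid, "raster_grid"))
  nb <- n_bands(grid)
  rows <- lapply(seq_len(nb), function(b) {
    v <- grid$values[, , b]
    v <- v[!is.na(v)]
    tibble::tibble(band = grid$band_names[b],
                   mean = mean(v), sd = sd_pop(v),
                   min = min(v), max = max(v), n_valid = length(v))
  })
  do.call(rbind, rows)
}

# population standard deviation (defined for n = 1)
sd_pop <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}
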