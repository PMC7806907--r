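#' Synthetic forest scene specification
#'
#' Defines a seeded synthetic study scene: overlapping tree crowns of up to
#' six tree classes over a non-forest background, with class-specific base
#' colour, class-specific fine-scale foliage texture (band-limited noise),
#' and a cone-shaped canopy surface per crown in the DSM. The defaults
#' emulate a mixed conifer/broad-leaved stand imaged at 5 cm ground
#' sampling distance: a 512 x 512 px scene (about 26 m across) with 40
#' crowns of 1-2 m radius.
#'
#' Class texture is governed by a per-class correlation length (pixels):
#' short lengths give high-frequency, high-contrast foliage speckle, long
#' lengths give smooth canopies, so classes are separable by co-occurrence
#' texture as well as by colour.
#'
#' @param size scene side length in pixels.
#' @param cell_size ground sampling distance in metres per pixel.
#' @param n_crowns number of crowns to place.
#' @param classes integer vector of tree classes used (subset of 1..6; class
#'   7 is the non-forest background).
#' @param class_colours 6 x 3 matrix of per-class RGB means (0-255).
#' @param colour_sd per-class RGB texture amplitude (grey levels).
#' @param texture_len per-class noise correlation length in pixels.
#' @param radius_range crown radius range in metres.
#' @param height_range crown apex height range in metres above background.
#' @param background_colour RGB of understory/bare ground.
#' @param background_sd,background_len background texture amplitude and
#'   correlation length.
#' @param overlap_allowance maximum allowed fractional overlap of crown
#'   radii: two crowns must satisfy `dist >= (1 - overlap_allowance) *
#'   (r1 + r2)`.
#' @param seed integer RNG seed; the whole scene is a pure function of the
#'   spec.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(size = 512L, cell_size = 0.05, n_crowns = 40L,
                       classes = 1:6,
                       class_colours = default_class_colours(),
                       colour_sd = c(18, 20, 16, 13, 16, 11),
                       texture_len = c(0.8, 2, 3.5, 5, 7, 10),
                       radius_range = c(1.0, 2.0),
                       height_range = c(6, 14),
                       background_colour = c(152, 118, 82),
                       background_sd = 8, background_len = 12,
                       overlap_allowance = 0.15, seed = 42L) {
  stopifnot(size >= 32, cell_size > 0, n_crowns >= length(classes),
            all(classes %in% 1:6), all(radius_range > 0),
            overlap_allowance >= 0, overlap_allowance < 1)
  structure(list(size = as.integer(size), cell_size = cell_size,
                 n_crowns = as.integer(n_crowns), classes = as.integer(classes),
                 class_colours = class_colours, colour_sd = colour_sd,
                 texture_len = texture_len, radius_range = radius_range,
                 height_range = height_range,
                 background_colour = background_colour,
                 background_sd = background_sd, background_len = background_len,
                 overlap_allowance = overlap_allowance,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Default per-class canopy colours
#'
#' Autumn-season palette for the six tree classes (rows): deciduous
#' broad-leaved, deciduous coniferous, evergreen broad-leaved,
#' hinoki cypress (*Chamaecyparis obtusa*), slash/loblolly pine
#' (*Pinus elliottii* / *P. taeda*), eastern white pine (*P. strobus*).
#'
#' @return 6 x 3 numeric matrix of RGB means in 0-255.
#' @export
default_class_colours <- function() {
  matrix(c(226, 158,  60,   # 1 deciduous broad-leaved (autumn orange)
           138,  66,  44,   # 2 deciduous coniferous (rust red-brown)
            34,  84,  40,   # 3 evergreen broad-leaved (dark green)
           118, 164, 106,   # 4 Chamaecyparis obtusa (pale yellow-green)
           128, 140,  46,   # 5 Pinus elliottii / taeda (olive)
            50,  96, 152),  # 6 Pinus strobus (blue-green)
         ncol = 3, byrow = TRUE)
}

#' The seven-class labelling scheme
#'
#' @return character vector of the 7 class names, in label order 1..7.
#' @export
class_labels <- function() {
  c("deciduous broad-leaved tree", "deciduous coniferous tree",
    "evergreen broad-leaved tree", "Chamaecyparis obtusa",
    "Pinus elliottii or Pinus taeda", "Pinus strobus", "non-forest")
}

# band-limited (low-pass filtered) unit-variance Gaussian noise field,
# correlation length `len` pixels; separable Gaussian smoothing via FFT-free
# row/column convolution with reflected edges
noise_field <- function(nr, nc, len) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (len > 0.5) {
    sigma <- len / 2
    half <- max(1L, ceiling(3 * sigma))
    k <- stats::dnorm(seq(-half, half), sd = sigma)
    k <- k / sum(k)
    z <- apply(z, 2, function(col) conv_reflect(col, k))
    z <- t(apply(z, 1, function(row) conv_reflect(row, k)))
  }
  s <- stats::sd(as.vector(z))
  if (s > 0) z <- z / s
  z
}

conv_reflect <- function(x, k) {
  half <- (length(k) - 1L) / 2
  n <- length(x)
  idx <- c(rev(seq_len(min(half, n))), seq_len(n),
           n + 1 - rev(seq_len(min(half, n))))
  # if half > n the reflection above is short; clamp instead
  if (length(idx) < n + 2 * half) {
    idx <- pmin(pmax(seq(1 - half, n + half), 1), n)
  }
  xp <- x[idx]
  as.numeric(stats::filter(xp, k, sides = 2))[half + seq_len(n)]
}

#' Generate a synthetic forest scene
#'
#' Places crowns as jittered disks (random radius, bounded mutual overlap)
#' with class-specific base colour plus band-limited noise texture of
#' class-specific correlation length; the DSM is a gently sloping ground
#' plane plus one cone per crown (apex at the crown centre, height falling
#' linearly to zero at the crown edge; overlapping crowns take the maximum,
#' i.e. canopy layering). Reference crown polygons are the disk outlines
#' clipped to the scene, labelled with their class. Fully deterministic for
#' a fixed spec (including its seed).
#'
#' @param spec a [scene_spec].
#' @return list with `ortho` (3-band byte [raster_grid]), `dsm`
#'   ([surface_model]), `references` (list of features with `polygon`
#'   matrix, `id`, `class`), and `crowns` (tibble of centre, radius, class,
#'   apex height per crown).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  n <- spec$size
  cs <- spec$cell_size
  ext <- n * cs

  # crown placement with bounded retries
  classes <- rep(spec$classes, length.out = spec$n_crowns)
  classes <- sample(classes)  # shuffle class order across the scene
  placed <- list()
  for (k in seq_len(spec$n_crowns)) {
    r <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
    ok <- FALSE
    for (try in 1:400) {
      cx <- stats::runif(1, r * 0.4, ext - r * 0.4)
      cy <- stats::runif(1, r * 0.4, ext - r * 0.4)
      ok <- TRUE
      for (p in placed) {
        if (sqrt((cx - p$x)^2 + (cy - p$y)^2) <
            (1 - spec$overlap_allowance) * (r + p$r)) { ok <- FALSE; break }
      }
      if (ok) break
    }
    if (!ok) {
      stop("could not place crown ", k,
           " within the overlap allowance after bounded retries; ",
           "reduce n_crowns or raise overlap_allowance")
    }
    placed[[k]] <- list(x = cx, y = cy, r = r, class = classes[k],
                        h = stats::runif(1, spec$height_range[1],
                                         spec$height_range[2]))
  }
  crowns <- tibble::tibble(
    id = seq_along(placed),
    x = vapply(placed, `[[`, 0, "x"), y = vapply(placed, `[[`, 0, "y"),
    radius = vapply(placed, `[[`, 0, "r"),
    class = vapply(placed, `[[`, 0L, "class"),
    height = vapply(placed, `[[`, 0, "h"))

  # pixel-centre coordinates (map frame: y decreases with row)
  px <- (seq_len(n) - 0.5) * cs          # x by column
  py <- ext - (seq_len(n) - 0.5) * cs    # y by row
  X <- matrix(px, n, n, byrow = TRUE)
  Y <- matrix(py, n, n)

  # background
  ortho <- array(0, c(n, n, 3))
  bg_noise <- noise_field(n, n, spec$background_len)
  for (b in 1:3) {
    ortho[, , b] <- spec$background_colour[b] +
      spec$background_sd * bg_noise +
      4 * matrix(stats::rnorm(n * n), n, n)
  }
  dsm <- 100 + 0.02 * X + 0.01 * Y   # gently sloping ground plane
  label <- matrix(0L, n, n)

  # per-class shared texture fields (one field per class keeps texture
  # statistics homogeneous within a class)
  tex <- lapply(1:6, function(cl) {
    if (cl %in% crowns$class) noise_field(n, n, spec$texture_len[cl]) else NULL
  })

  for (k in seq_len(nrow(crowns))) {
    cr <- crowns[k, ]
    d <- sqrt((X - cr$x)^2 + (Y - cr$y)^2)
    inside <- d <= cr$radius
    cl <- cr$class
    shade <- 1 - 0.25 * (d / cr$radius)^2   # limb darkening toward the rim
    for (b in 1:3) {
      band <- ortho[, , b]
      band[inside] <- spec$class_colours[cl, b] * shade[inside] +
        spec$colour_sd[cl] * tex[[cl]][inside]
      ortho[, , b] <- band
    }
    cone <- dsm + cr$height * (1 - d / cr$radius)
    upd <- inside & (cone > dsm | label == 0L)
    dsm[inside] <- pmax(dsm[inside], cone[inside])
    label[inside] <- cr$id
  }
  ortho <- round(pmin(pmax(ortho, 0), 255))

  refs <- lapply(seq_len(nrow(crowns)), function(k) {
    cr <- crowns[k, ]
    th <- seq(0, 2 * pi, length.out = 65)[-65]
    ring <- cbind(cr$x + cr$radius * cos(th), cr$y + cr$radius * sin(th))
    ring <- clip_ring_rect(ring, 0, ext, 0, ext)
    list(polygon = ring, id = cr$id, class = cr$class)
  })

  list(
    ortho = raster_grid(ortho, origin = c(0, ext), cell_size = cs,
                        band_names = c("R", "G", "B")),
    dsm = surface_model(dsm, cell_size = cs, origin = c(0, ext)),
    references = refs,
    crowns = crowns
  )
}

# Sutherland-Hodgman clip of a ring against an axis-aligned rectangle
clip_ring_rect <- function(ring, xmin, xmax, ymin, ymax) {
  clip_half <- function(r, inside, intersect) {
    if (nrow(r) == 0L) return(r)
    out <- matrix(0, 0, 2)
    np <- nrow(r)
    for (i in seq_len(np)) {
      cur <- r[i, ]; prev <- r[if (i == 1L) np else i - 1L, ]
      ci <- inside(cur); pi <- inside(prev)
      if (ci) {
        if (!pi) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (pi) {
        out <- rbind(out, intersect(prev, cur))
      }
    }
    out
  }
  ix <- function(p, q, coord, val) {
    t <- (val - p[coord]) / (q[coord] - p[coord])
    p + t * (q - p)
  }
  r <- ring
  r <- clip_half(r, function(p) p[1] >= xmin, function(p, q) ix(p, q, 1, xmin))
  r <- clip_half(r, function(p) p[1] <= xmax, function(p, q) ix(p, q, 1, xmax))
  r <- clip_half(r, function(p) p[2] >= ymin, function(p, q) ix(p, q, 2, ymin))
  r <- clip_half(r, function(p) p[2] <= ymax, function(p, q) ix(p, q, 2, ymax))
  r
}

#' Rasterize reference crowns to a label raster
#'
#' Pixel-centre-in-polygon test; where crowns overlap, later-placed crowns
#' overwrite earlier ones (canopy layering). Background is 0.
#'
#' @param references list of features with `polygon` (map coordinates) and
#'   `id`.
#' @param grid a [raster_grid] or [surface_model] defining the target grid.
#' @return integer matrix of reference ids (0 = background).
#' @export
rasterize_references <- function(references, grid) {
  gi <- grid_info(grid)
  out <- matrix(0L, gi$nrow, gi$ncol)
  px <- gi$origin[1] + (seq_len(gi$ncol) - 0.5) * gi$cell
  py <- gi$origin[2] - (seq_len(gi$nrow) - 0.5) * gi$cell
  for (f in references) {
    rings <- polygon_rings(f$polygon)
    bb <- apply(rings[[1]], 2, range)
    cols <- which(px >= bb[1, 1] - gi$cell & px <= bb[2, 1] + gi$cell)
    rows <- which(py >= bb[1, 2] - gi$cell & py <= bb[2, 2] + gi$cell)
    if (!length(rows) || !length(cols)) next
    XX <- matrix(px[cols], length(rows), length(cols), byrow = TRUE)
    YY <- matrix(py[rows], length(rows), length(cols))
    inside <- point_in_polygon(as.vector(XX), as.vector(YY), f$polygon)
    m <- matrix(inside, length(rows), length(cols))
    sub <- out[rows, cols, drop = FALSE]
    sub[m] <- as.integer(f$id)
    out[rows, cols] <- sub
  }
  out
}

# even-odd point-in-polygon over all rings (holes excluded automatically)
point_in_polygon <- function(x, y, poly) {
  rings <- polygon_rings(poly)
  inside <- rep(FALSE, length(x))
  for (r in rings) {
    res <- pracma::inpolygon(x, y, r[, 1], r[, 2], boundary = TRUE)
    inside <- xor(inside, res)
  }
  inside
}

grid_info <- function(grid) {
  if (inherits(grid, "raster_grid")) {
    d <- dim(grid$values)
    list(nrow = d[1], ncol = d[2], cell = grid$cell_size, origin = grid$origin)
  } else if (inherits(grid, "surface_model")) {
    list(nrow = nrow(grid$elevation), ncol = ncol(grid$elevation),
         cell = grid$cell_size, origin = grid$origin)
  } else if (is.matrix(grid)) {
    list(nrow = nrow(grid), ncol = ncol(grid), cell = 1, origin = c(0, nrow(grid)))
  } else stop("unsupported grid object")
}
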