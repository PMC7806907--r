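#' Multiresolution segmentation parameters
#'
#' The merge threshold is `scale^2`: larger scale lets merging run further
#' and yields fewer, larger segments. `w_shape` balances colour versus shape
#' heterogeneity; `w_compact` balances compactness versus smoothness inside
#' the shape term. `layer_weights` weight the bands of the layer stack in
#' the colour term (zero removes a layer's influence).
#'
#' @param scale positive merge-threshold parameter.
#' @param w_shape shape weight in `[0, 1)`.
#' @param w_compact compactness weight in `[0, 1]`.
#' @param layer_weights nonnegative per-band weights (recycled/validated
#'   against the stack at segmentation time); at least one must be positive.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(scale = 20, w_shape = 0.1, w_compact = 0.5,
                                layer_weights = NULL) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0,
            w_shape >= 0, w_shape < 1, w_compact >= 0, w_compact <= 1)
  if (!is.null(layer_weights)) {
    stopifnot(all(layer_weights >= 0), any(layer_weights > 0))
  }
  structure(list(scale = scale, w_shape = w_shape, w_compact = w_compact,
                 layer_weights = layer_weights),
            class = "segmentation_params")
}

#' Per-segment objects of a label grid
#'
#' Recomputes, from the label grid and the layer stack, the statistics the
#' merge criterion maintains incrementally: pixel count, per-band mean and
#' population SD, perimeter (pixel-edge length, image border included),
#' bounding box, and the 4-adjacency structure with shared boundary lengths.
#'
#' @param labels integer matrix of segment ids (positive).
#' @param stack a [raster_grid] (or plain matrix) aligned with `labels`.
#' @return tibble keyed by `id` with list-columns `mean`, `sd` (per band),
#'   `bbox` (`minr, maxr, minc, maxc`) and `adjacency` (named integer
#'   vector: neighbour id -> shared edge length).
#' @export
segment_objects <- function(labels, stack) {
  vals <- if (inherits(stack, "raster_grid")) stack$values
  else if (is.array(stack) && length(dim(stack)) == 3L) stack
  else array(stack, c(dim(stack), 1L))
  stopifnot(all(dim(vals)[1:2] == dim(labels)))
  u <- sort(unique(as.vector(labels)))
  f <- factor(as.vector(labels), levels = u)
  ids <- as.integer(u)
  nb <- dim(vals)[3]
  n <- as.integer(table(f))
  sums <- vapply(seq_len(nb), function(b)
    rowsum(as.vector(vals[, , b]), f)[, 1], numeric(length(ids)))
  sqs <- vapply(seq_len(nb), function(b)
    rowsum(as.vector(vals[, , b])^2, f)[, 1], numeric(length(ids)))
  if (length(ids) == 1L) { sums <- matrix(sums, 1); sqs <- matrix(sqs, 1) }
  means <- sums / n
  vars <- pmax(sqs / n - means^2, 0)

  ri <- row(labels); ci <- col(labels)
  minr <- tapply(ri, f, min); maxr <- tapply(ri, f, max)
  minc <- tapply(ci, f, min); maxc <- tapply(ci, f, max)

  # adjacency: 4-neighbour label pairs with shared edge counts
  nr <- nrow(labels); nc <- ncol(labels)
  hp <- cbind(as.vector(labels[, -nc]), as.vector(labels[, -1]))
  vp <- cbind(as.vector(labels[-nr, ]), as.vector(labels[-1, ]))
  pairs <- rbind(hp, vp)
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  key <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  cnt <- table(key)
  ka <- as.integer(sub(" .*", "", names(cnt)))
  kb <- as.integer(sub(".* ", "", names(cnt)))
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(ka)) {
    a <- as.character(ka[i]); b <- as.character(kb[i]); m <- as.integer(cnt[i])
    adj[[a]] <- c(adj[[a]], stats::setNames(m, b))
    adj[[b]] <- c(adj[[b]], stats::setNames(m, a))
  }

  # perimeter = 4n - 2 * internal same-label edges
  hsame <- labels[, -nc][labels[, -nc] == labels[, -1]]
  vsame <- labels[-nr, ][labels[-nr, ] == labels[-1, ]]
  tb <- table(factor(c(hsame, vsame), levels = levels(f)))
  perim <- 4 * n - 2 * as.integer(tb)

  tibble::tibble(
    id = ids, n = n,
    mean = lapply(seq_along(ids), function(i) means[i, ]),
    sd = lapply(seq_along(ids), function(i) sqrt(vars[i, ])),
    sum = lapply(seq_along(ids), function(i) sums[i, ]),
    sumsq = lapply(seq_along(ids), function(i) sqs[i, ]),
    perimeter = perim,
    bbox = lapply(seq_along(ids), function(i)
      c(minr = minr[[i]], maxr = maxr[[i]], minc = minc[[i]], maxc = maxc[[i]])),
    adjacency = lapply(as.character(ids), function(k)
      if (is.null(adj[[k]])) stats::setNames(integer(0), character(0)) else adj[[k]])
  )
}

#' Heterogeneity increase of merging two adjacent segments
#'
#' The merge criterion of bottom-up multiresolution segmentation:
#' \deqn{f = (1 - w_{shape})\,\Delta h_{colour} + w_{shape}\,\Delta h_{shape}}
#' with the colour term
#' \deqn{\Delta h_{colour} = \sum_c w_c\,(n_m \sigma_{c,m} -
#'   (n_a \sigma_{c,a} + n_b \sigma_{c,b}))}
#' (population SDs) and the shape term mixing size-weighted increases of
#' compactness (`perimeter / sqrt(n)`) and smoothness
#' (`perimeter / bounding-box perimeter`) with weight `w_compact`. A merge
#' is admissible when `f < scale^2`.
#'
#' @param a,b rows of a [segment_objects()] table (as lists, e.g.
#'   `objects[i, ]` or `as.list(objects[i, ])`); must be adjacent.
#' @param params a [segmentation_params]; `layer_weights` default to equal.
#' @return the heterogeneity increase `f`.
#' @export
merge_cost <- function(a, b, params) {
  a <- as_segment_row(a); b <- as_segment_row(b)
  if (!as.character(b$id) %in% names(a$adjacency)) {
    stop("segments ", a$id, " and ", b$id, " are not adjacent")
  }
  shared <- a$adjacency[[as.character(b$id)]]
  nbands <- length(a$mean)
  w <- params$layer_weights
  if (is.null(w)) w <- rep(1, nbands)
  stopifnot(length(w) == nbands)
  n_m <- a$n + b$n
  sum_m <- a$sum + b$sum
  sq_m <- a$sumsq + b$sumsq
  var_m <- pmax(sq_m / n_m - (sum_m / n_m)^2, 0)
  d_colour <- sum(w * (n_m * sqrt(var_m) - (a$n * a$sd + b$n * b$sd)))
  p_m <- a$perimeter + b$perimeter - 2 * shared
  bbp <- function(bb) 2 * ((bb["maxr"] - bb["minr"] + 1) +
                             (bb["maxc"] - bb["minc"] + 1))
  bb_m <- c(minr = min(a$bbox["minr"], b$bbox["minr"]),
            maxr = max(a$bbox["maxr"], b$bbox["maxr"]),
            minc = min(a$bbox["minc"], b$bbox["minc"]),
            maxc = max(a$bbox["maxc"], b$bbox["maxc"]))
  names(bb_m) <- c("minr", "maxr", "minc", "maxc")
  d_cmp <- p_m * sqrt(n_m) -
    (a$perimeter * sqrt(a$n) + b$perimeter * sqrt(b$n))
  d_smo <- n_m * p_m / bbp(bb_m) -
    (a$n * a$perimeter / bbp(a$bbox) + b$n * b$perimeter / bbp(b$bbox))
  d_shape <- params$w_compact * d_cmp + (1 - params$w_compact) * d_smo
  unname((1 - params$w_shape) * d_colour + params$w_shape * d_shape)
}

as_segment_row <- function(x) {
  if (inherits(x, "data.frame")) {
    stopifnot(nrow(x) == 1L)
    x <- lapply(x, function(col) if (is.list(col)) col[[1]] else col)
  }
  x
}

#' Segment a layer stack into crown objects
#'
#' Bottom-up region merging from single-pixel seeds: in seeded random scan
#' order, each segment proposes a merge with its cheapest neighbour; the
#' merge executes only if the pair is mutually best fitting and the
#' heterogeneity increase is below `scale^2`. Sweeps repeat until no
#' admissible merge remains. Deterministic for fixed input, params and seed.
#'
#' @param stack a [raster_grid] (any band count) — typically the 5-band
#'   stack from [stack_layers()]; its `layer_weights` are used when
#'   `params$layer_weights` is `NULL`.
#' @param params a [segmentation_params].
#' @param seed integer seed for the scan order.
#' @return an object of class `segment_map`: `labels` (integer matrix,
#'   contiguous ids from 1), `objects` ([segment_objects()] table),
#'   `cell_size`, `origin`, `params`, `seed`.
#' @export
multiresolution_segment <- function(stack, params = segmentation_params(),
                                    seed = 1L) {
  stopifnot(inherits(stack, "raster_grid"))
  d <- dim(stack$values)
  if (d[1] == 0L || d[2] == 0L) stop("empty raster")
  w <- params$layer_weights
  if (is.null(w)) w <- stack$layer_weights
  if (is.null(w)) w <- rep(1, d[3])
  stopifnot(length(w) == d[3], all(w >= 0), any(w > 0))
  labels <- mrs_segment_cpp(as.numeric(stack$values), d[1], d[2], d[3],
                            as.numeric(w), params$scale, params$w_shape,
                            params$w_compact, as.integer(seed), 10000L)
  params$layer_weights <- w
  structure(list(labels = labels,
                 objects = segment_objects(labels, stack),
                 cell_size = stack$cell_size, origin = stack$origin,
                 params = params, seed = as.integer(seed)),
            class = "segment_map")
}

#' @export
print.segment_map <- function(x, ...) {
  cat(sprintf("<segment_map> %d x %d px, %d segments (scale %.3g)\n",
              nrow(x$labels), ncol(x$labels), nrow(x$objects),
              x$params$scale))
  invisible(x)
}

#' Polygonize a segment map
#'
#' Traces each segment's boundary along pixel edges into an outer ring plus
#' holes. In pixel coordinates the polygon area equals the pixel count
#' exactly; with `world = TRUE` vertices are mapped through the
#' geotransform (area scales by `cell_size^2`).
#'
#' @param segmap a [segment_map], or a plain integer label matrix.
#' @param world map vertices to world coordinates via the geotransform.
#' @return list of features `(polygon, id)`; `polygon` is a ring matrix or
#'   an `outer`/`holes` list.
#' @export
polygonize_segments <- function(segmap, world = inherits(segmap, "segment_map")) {
  labels <- if (inherits(segmap, "segment_map")) segmap$labels else segmap
  ids <- sort(unique(as.vector(labels)))
  ids <- ids[ids > 0]
  feats <- lapply(ids, function(id) {
    rings <- trace_mask_rings(labels == id)
    if (length(rings) == 1L) {
      poly <- rings[[1]]
    } else {
      # outer rings are traced clockwise in the y-down pixel frame
      # (positive shoelace), holes counter-clockwise (negative)
      sgn <- vapply(rings, ring_area_signed, 0)
      if (sum(sgn > 0) != 1L) {
        stop("segment ", id, " is not 4-connected; cannot polygonize")
      }
      poly <- list(outer = rings[[which(sgn > 0)]], holes = rings[sgn < 0])
    }
    if (world) poly <- polygon_pixel_to_world(poly, segmap)
    list(polygon = poly, id = id)
  })
  feats
}

polygon_pixel_to_world <- function(poly, segmap) {
  cs <- segmap$cell_size; o <- segmap$origin
  tx <- function(r) cbind(o[1] + r[, 1] * cs, o[2] - r[, 2] * cs)
  if (is.matrix(poly)) return(tx(poly))
  list(outer = tx(poly$outer), holes = lapply(poly$holes, tx))
}

# Trace boundary rings of a logical mask. Pixel (r, c) spans x in [c-1, c],
# y in [r-1, r] (y increasing downward). Directed boundary edges keep the
# interior on a consistent side; at degree-4 lattice points the sharpest
# turn is taken so diagonally touching boundary lobes stay separate.
trace_mask_rings <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  inside <- function(r, c) pad[r + 1, c + 1]
  # collect directed edges as (x0, y0, x1, y1)
  idx <- which(mask, arr.ind = TRUE)
  edges <- matrix(0, 0, 4)
  er <- idx[, 1]; ec <- idx[, 2]
  north <- !pad[cbind(er, ec + 1)]
  east  <- !pad[cbind(er + 1, ec + 2)]
  south <- !pad[cbind(er + 2, ec + 1)]
  west  <- !pad[cbind(er + 1, ec)]
  edges <- rbind(
    cbind(ec[north] - 1, er[north] - 1, ec[north], er[north] - 1),  # top, ->
    cbind(ec[east], er[east] - 1, ec[east], er[east]),              # right, v
    cbind(ec[south], er[south], ec[south] - 1, er[south]),          # bottom, <-
    cbind(ec[west] - 1, er[west], ec[west] - 1, er[west] - 1)       # left, ^
  )
  if (nrow(edges) == 0L) return(list())
  # map start vertex -> edge indices
  keyv <- function(x, y) x * (nr + 2) + y
  starts <- keyv(edges[, 1], edges[, 2])
  by_start <- split(seq_len(nrow(edges)), starts)
  used <- rep(FALSE, nrow(edges))
  rings <- list()
  for (e0 in seq_len(nrow(edges))) {
    if (used[e0]) next
    verts <- vector("list", 64L)
    verts[[1L]] <- edges[e0, 1:2]
    nv <- 1L
    cur <- e0
    repeat {
      used[cur] <- TRUE
      head <- edges[cur, 3:4]
      if (all(head == verts[[1L]])) break
      nv <- nv + 1L
      verts[[nv]] <- head
      cand <- by_start[[as.character(keyv(head[1], head[2]))]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) stop("boundary tracing failed (open ring)")
      if (length(cand) == 1L) {
        cur <- cand
      } else {
        # degree-4 vertex: take the sharpest right turn relative to the
        # incoming direction (interior stays on the consistent side)
        din <- edges[cur, 3:4] - edges[cur, 1:2]
        scores <- vapply(cand, function(e) {
          dout <- edges[e, 3:4] - edges[e, 1:2]
          # cross product z (y-down frame): positive = clockwise turn,
          # which keeps the trace on the current boundary lobe
          din[1] * dout[2] - din[2] * dout[1]
        }, 0)
        cur <- cand[which.max(scores)]
      }
    }
    rings[[length(rings) + 1L]] <- do.call(rbind, verts[seq_len(nv)])
  }
  rings
}
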