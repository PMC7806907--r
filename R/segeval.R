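#' Overlap thresholds of the five-category crown matching scheme
#'
#' A segment is scored against reference crowns by the fraction of each
#' reference it covers: more than 80% of one crown is *Matched*, 60-80% is
#' *Nearly matched*, 20-60% is *Split*; overlaps above 20% with two or more
#' crowns make the segment *Merged* (one-class or multi-class by the crown
#' labels); when no overlap exceeds 20% the segment is *Fragmented*.
#' Boundary values close downward: exactly 0.60 is Split, exactly 0.20 does
#' not count toward Merged.
#'
#' @param matched_min,nearly_min,split_min threshold fractions,
#'   `0 < split_min < nearly_min < matched_min < 1`.
#' @return an object of class `match_thresholds`.
#' @export
match_thresholds <- function(matched_min = 0.80, nearly_min = 0.60,
                             split_min = 0.20) {
  stopifnot(0 < split_min, split_min < nearly_min, nearly_min < matched_min,
            matched_min < 1)
  structure(list(matched_min = matched_min, nearly_min = nearly_min,
                 split_min = split_min), class = "match_thresholds")
}

match_categories <- c("Matched", "NearlyMatched", "Split",
                      "MergedOneClass", "MergedMultiClass", "Fragmented")

#' Overlap of a segment polygon with a reference crown
#'
#' `area(segment intersect reference) / area(reference)` by default (the
#' segment "covering" the crown), or intersection-over-union with
#' `mode = "iou"`. Convex references are clipped exactly
#' (Sutherland-Hodgman); non-convex references fall back to dense pixel
#' rasterization of both polygons.
#'
#' @param segment_polygon ring matrix or `outer`/`holes` list.
#' @param reference a feature with `polygon` (and optionally `class`, `id`),
#'   or a bare ring matrix.
#' @param mode `"reference"` (fraction of reference area) or `"iou"`.
#' @param raster_res grid resolution (cells across the joint bounding box)
#'   for the non-convex fallback.
#' @return overlap fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(segment_polygon, reference,
                             mode = c("reference", "iou"), raster_res = 512L) {
  mode <- match.arg(mode)
  ref_poly <- if (is.list(reference) && !is.null(reference$polygon))
    reference$polygon else reference
  a_ref <- polygon_area(ref_poly)
  if (a_ref <= 0) stop("reference crown has zero area")
  a_seg <- polygon_area(segment_polygon)
  a_int <- intersection_area(segment_polygon, ref_poly, raster_res)
  if (a_int < 1e-12 * a_ref) a_int <- 0  # clipping round-off
  if (mode == "reference") {
    min(a_int / a_ref, 1)
  } else {
    a_int / (a_seg + a_ref - a_int)
  }
}

intersection_area <- function(subject, clip, raster_res = 512L) {
  bb1 <- apply(do.call(rbind, polygon_rings(subject)), 2, range)
  bb2 <- apply(do.call(rbind, polygon_rings(clip)), 2, range)
  if (any(bb1[1, ] > bb2[2, ]) || any(bb2[1, ] > bb1[2, ])) return(0)
  if (is.matrix(clip) && is_convex_ring(clip)) {
    rings <- polygon_rings(subject)
    outer <- ring_clip_convex(rings[[1]], clip)
    a <- if (nrow(outer) >= 3) abs(ring_area_signed(outer)) else 0
    if (length(rings) > 1L) {
      for (h in rings[-1]) {
        hc <- ring_clip_convex(h, clip)
        if (nrow(hc) >= 3) a <- a - abs(ring_area_signed(hc))
      }
    }
    return(max(a, 0))
  }
  # non-convex clip: dense rasterization of the joint bounding box
  lo <- pmin(bb1[1, ], bb2[1, ]); hi <- pmax(bb1[2, ], bb2[2, ])
  if (any(hi <= lo)) return(0)
  step <- max(hi - lo) / raster_res
  xs <- seq(lo[1] + step / 2, hi[1], by = step)
  ys <- seq(lo[2] + step / 2, hi[2], by = step)
  X <- rep(xs, times = length(ys)); Y <- rep(ys, each = length(xs))
  ins <- point_in_polygon(X, Y, subject) & point_in_polygon(X, Y, clip)
  sum(ins) * step^2
}

is_convex_ring <- function(r) {
  r <- open_ring(r)
  n <- nrow(r)
  if (n < 3L) return(FALSE)
  d <- rbind(r[-1, , drop = FALSE], r[1, , drop = FALSE]) - r
  cr <- d[, 1] * c(d[-1, 2], d[1, 2]) - d[, 2] * c(d[-1, 1], d[1, 1])
  all(cr >= -1e-12 * max(abs(cr))) || all(cr <= 1e-12 * max(abs(cr)))
}

# Sutherland-Hodgman clip of `subject` ring against convex `clip` ring,
# vectorized over subject vertices per clip edge
ring_clip_convex <- function(subject, clip) {
  clip <- open_ring(clip)
  if (ring_area_signed(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), ]
  out <- open_ring(subject)
  nclip <- nrow(clip)
  for (i in seq_len(nclip)) {
    np <- nrow(out)
    if (np == 0L) break
    A <- clip[i, ]; B <- clip[if (i == nclip) 1L else i + 1L, ]
    ex <- B[1] - A[1]; ey <- B[2] - A[2]
    s <- ex * (out[, 2] - A[2]) - ey * (out[, 1] - A[1])
    sp <- s[c(np, seq_len(np - 1L))]          # previous vertex side
    prev <- out[c(np, seq_len(np - 1L)), , drop = FALSE]
    cross <- (s >= 0) != (sp >= 0)
    t <- ifelse(cross, sp / (sp - s), 0)
    ints <- prev + t * (out - prev)
    # emit, in order per vertex: intersection (if edge crosses), then the
    # vertex itself (if inside)
    cand <- rbind(ints, out)
    ord <- as.vector(rbind(seq_len(np), np + seq_len(np)))
    keepm <- as.vector(rbind(cross, s >= 0))
    out <- cand[ord, , drop = FALSE][keepm, , drop = FALSE]
  }
  out
}

#' Categorize one segment against the reference crowns
#'
#' Implements the five-category scheme: let `S` be the references whose
#' overlap fraction exceeds `split_min`. `|S| = 0` is Fragmented; `|S| >= 2`
#' is MergedOneClass when all of `S` share one class, otherwise
#' MergedMultiClass; `|S| = 1` with overlap `o` is Matched when
#' `o > matched_min`, NearlyMatched when `nearly_min < o <= matched_min`,
#' otherwise Split.
#'
#' @param segment_polygon segment outline.
#' @param references list of features with `polygon` and `class`.
#' @param thresholds a [match_thresholds].
#' @param mode overlap mode passed to [overlap_fraction()].
#' @return a length-1 character, one of the six category names, with the
#'   per-reference overlaps as attribute `overlaps`.
#' @export
categorize_segment <- function(segment_polygon, references,
                               thresholds = match_thresholds(),
                               mode = "reference") {
  if (length(references) == 0L) stop("at least one reference crown required")
  ov <- vapply(references, function(rf)
    overlap_fraction(segment_polygon, rf, mode = mode), 0)
  S <- which(ov > thresholds$split_min)
  cat_name <- if (length(S) == 0L) {
    "Fragmented"
  } else if (length(S) >= 2L) {
    cls <- vapply(references[S], function(rf) as.integer(rf$class), 0L)
    if (length(unique(cls)) == 1L) "MergedOneClass" else "MergedMultiClass"
  } else {
    o <- ov[S]
    if (o > thresholds$matched_min) "Matched"
    else if (o > thresholds$nearly_min) "NearlyMatched"
    else "Split"
  }
  structure(cat_name, overlaps = ov)
}

#' Tabulate crown-matching statistics per named area
#'
#' Scores every evaluated segment of a segment map against the reference
#' crowns and tabulates the category counts per named evaluation area
#' (columns: Matched, Nearly matched, Split, Merged one-class, Merged
#' multi-class, Fragmented). A segment is assigned to the area containing
#' its centroid. Segments that intersect no reference and whose centroid
#' lies outside every reference are treated as non-forest background and
#' excluded, unless a non-forest (class 7) reference exists.
#'
#' @param segmap a [segment_map].
#' @param references list of reference features (`polygon`, `class`, `id`).
#' @param thresholds a [match_thresholds].
#' @param areas named list of area polygons (map coordinates); `NULL` scores
#'   the whole scene as one area named `"scene"`.
#' @param mode overlap mode.
#' @return tibble: one row per area with the six category counts and
#'   `n_segments`; attribute `segment_categories` holds the per-segment
#'   table.
#' @export
tabulate_matches <- function(segmap, references,
                             thresholds = match_thresholds(),
                             areas = NULL, mode = "reference") {
  feats <- polygonize_segments(segmap)
  has_nonforest <- any(vapply(references, function(r)
    as.integer(r$class) == 7L, TRUE))
  if (is.null(areas)) {
    ext <- c(ncol(segmap$labels), nrow(segmap$labels)) * segmap$cell_size
    areas <- list(scene = cbind(
      c(segmap$origin[1], segmap$origin[1] + ext[1],
        segmap$origin[1] + ext[1], segmap$origin[1]),
      c(segmap$origin[2] - ext[2], segmap$origin[2] - ext[2],
        segmap$origin[2], segmap$origin[2])))
  }
  per_seg <- lapply(feats, function(f) {
    ctg <- categorize_segment(f$polygon, references, thresholds, mode)
    ov <- attr(ctg, "overlaps")
    centroid <- polygon_centroid(f$polygon)
    in_any_ref <- any(vapply(references, function(rf)
      point_in_polygon(centroid[1], centroid[2], rf$polygon), TRUE))
    background <- !has_nonforest && all(ov == 0) && !in_any_ref
    area_name <- NA_character_
    for (an in names(areas)) {
      if (point_in_polygon(centroid[1], centroid[2], areas[[an]])) {
        area_name <- an; break
      }
    }
    tibble::tibble(id = f$id, category = as.character(ctg),
                   area = area_name, excluded = background)
  })
  per_seg <- do.call(rbind, per_seg)
  evald <- per_seg[!per_seg$excluded & !is.na(per_seg$area), ]
  rows <- lapply(names(areas), function(an) {
    sub <- evald[evald$area == an, ]
    if (nrow(sub) == 0L) {
      warning("area '", an, "' contains no evaluated segments")
    }
    cnt <- table(factor(sub$category, levels = match_categories))
    tibble::tibble(area = an,
                   matched = as.integer(cnt["Matched"]),
                   nearly_matched = as.integer(cnt["NearlyMatched"]),
                   split = as.integer(cnt["Split"]),
                   merged_one_class = as.integer(cnt["MergedOneClass"]),
                   merged_multi_class = as.integer(cnt["MergedMultiClass"]),
                   fragmented = as.integer(cnt["Fragmented"]),
                   n_segments = nrow(sub))
  })
  out <- do.call(rbind, rows)
  attr(out, "segment_categories") <- per_seg
  out
}

#' Per-reference crown recovery
#'
#' For each reference crown, finds the segment covering it best and reports
#' that crown's recovery category: the category the best-covering segment
#' receives, from the crown's perspective (Matched when its best coverage
#' exceeds `matched_min`, and so on).
#'
#' @param segmap a [segment_map].
#' @param references list of reference features.
#' @param thresholds a [match_thresholds].
#' @return tibble: reference `id`, `class`, `best_overlap`, `best_segment`,
#'   `recovered` (best overlap above `nearly_min`, i.e. Matched or
#'   NearlyMatched).
#' @export
reference_recovery <- function(segmap, references,
                               thresholds = match_thresholds()) {
  feats <- polygonize_segments(segmap)
  rows <- lapply(references, function(rf) {
    ov <- vapply(feats, function(f)
      overlap_fraction(f$polygon, rf, mode = "reference"), 0)
    k <- which.max(ov)
    tibble::tibble(id = rf$id, class = as.integer(rf$class),
                   best_overlap = ov[k],
                   best_segment = feats[[k]]$id,
                   recovered = ov[k] > thresholds$nearly_min)
  })
  do.call(rbind, rows)
}
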