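#' Convert an RGB image to 8-bit greyscale
#'
#' Luminance weighting `0.299 R + 0.587 G + 0.114 B`, rounded to integers in
#' 0..255.
#'
#' @param rgb rows x cols x 3 array with values in 0..255.
#' @return integer-valued greyscale matrix.
#' @export
to_grey <- function(rgb) {
  if (is.matrix(rgb)) return(round(rgb))
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] >= 3L)
  round(0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3])
}

#' Quantize 8-bit grey values to fewer bits
#'
#' `level = floor(value / 2^(8 - bits_out))`, mapping 0..255 onto
#' `0 .. 2^bits_out - 1`. The default pipeline rescales to 5 bits
#' (32 levels) before co-occurrence computation to keep the matrix small.
#'
#' @param image matrix of values in `[0, 255]`.
#' @param bits_out target bit depth, 1..8.
#' @return integer matrix of grey levels.
#' @export
quantize_grey <- function(image, bits_out = 5L) {
  stopifnot(bits_out >= 1L, bits_out <= 8L)
  if (any(image < 0 | image > 255, na.rm = TRUE)) {
    stop("grey values must lie in [0, 255]")
  }
  lv <- floor(image / 2^(8L - bits_out))
  storage.mode(lv) <- "integer"
  lv
}

#' Default co-occurrence offsets
#'
#' Distance-1 offsets in the four directions 0, 45, 90 and 135 degrees;
#' combined with symmetric counting this gives the common rotation-robust
#' GLCM convention.
#'
#' @return 4 x 2 integer matrix of `(drow, dcol)` offsets.
#' @export
glcm_offsets <- function() {
  matrix(c(0L, 1L,    # 0 degrees
           -1L, 1L,   # 45 degrees
           -1L, 0L,   # 90 degrees
           -1L, -1L), # 135 degrees
         ncol = 2, byrow = TRUE)
}

#' Grey-level co-occurrence matrix of a window
#'
#' Counts co-occurring level pairs `(i, j)` at every offset over the whole
#' window, optionally symmetrized (counting both `(i, j)` and `(j, i)`), and
#' normalizes to sum 1. Entry `P[i+1, j+1]` houses the probability of level
#' pair `(i, j)` (levels are 0-based).
#'
#' @param window matrix of grey levels in `0 .. n_levels - 1`.
#' @param n_levels number of grey levels `N`.
#' @param offsets integer matrix of `(drow, dcol)` offsets.
#' @param symmetric count both orders of every pair.
#' @return an `N x N` matrix of class `glcm_matrix` summing to 1.
#' @export
compute_glcm <- function(window, n_levels = 32L, offsets = glcm_offsets(),
                         symmetric = TRUE) {
  stopifnot(is.matrix(window))
  if (any(window < 0 | window >= n_levels)) {
    stop("window levels must lie in [0, n_levels)")
  }
  nr <- nrow(window); nc <- ncol(window)
  counts <- matrix(0, n_levels, n_levels)
  any_pair <- FALSE
  for (o in seq_len(nrow(offsets))) {
    dr <- offsets[o, 1]; dc <- offsets[o, 2]
    ri <- seq_len(nr); ci <- seq_len(nc)
    ri <- ri[ri + dr >= 1 & ri + dr <= nr]
    ci <- ci[ci + dc >= 1 & ci + dc <= nc]
    if (!length(ri) || !length(ci)) next
    any_pair <- TRUE
    a <- window[ri, ci, drop = FALSE]
    b <- window[ri + dr, ci + dc, drop = FALSE]
    tab <- table(factor(a, levels = 0:(n_levels - 1)),
                 factor(b, levels = 0:(n_levels - 1)))
    counts <- counts + tab
    if (symmetric) counts <- counts + t(tab)
  }
  if (!any_pair) stop("window too small for every offset")
  P <- counts / sum(counts)
  class(P) <- c("glcm_matrix", class(P))
  attr(P, "symmetric") <- symmetric
  P
}

#' Five co-occurrence texture statistics
#'
#' For a normalized GLCM `P` with levels `i, j`:
#' angular second moment `sum P^2`; contrast `sum P (i-j)^2`; dissimilarity
#' `sum P |i-j|`; entropy `-sum P log P` (natural log, `0 log 0 := 0`);
#' homogeneity `sum P / (1 + (i-j)^2)`.
#'
#' @param P a [compute_glcm()] matrix (must sum to 1).
#' @return tibble with columns `asm`, `contrast`, `dissimilarity`,
#'   `entropy`, `homogeneity`.
#' @export
texture_stats <- function(P) {
  P <- unclass(P)
  if (abs(sum(P) - 1) > 1e-9) stop("GLCM must be normalized to sum 1")
  n <- nrow(P)
  i <- matrix(0:(n - 1), n, n)
  j <- t(i)
  d <- i - j
  nz <- P > 0
  tibble::tibble(
    asm = sum(P^2),
    contrast = sum(P * d^2),
    dissimilarity = sum(P * abs(d)),
    entropy = -sum(P[nz] * log(P[nz])),
    homogeneity = sum(P / (1 + d^2))
  )
}

#' Sliding-kernel texture maps
#'
#' Computes the five co-occurrence statistics at every pixel from the GLCM
#' of the centred `kernel_size x kernel_size` window. Pixels within
#' `(kernel_size - 1) / 2` of the image margin are `NA` (their window is
#' incomplete).
#'
#' @param image greyscale matrix in 0..255, or a pre-quantized level matrix
#'   if `quantized = TRUE`.
#' @param kernel_size odd window size >= 3.
#' @param n_levels grey levels after quantization (default 32 = 5-bit).
#' @param offsets,symmetric co-occurrence convention, see [compute_glcm()].
#' @param quantized set when `image` already holds levels in
#'   `0 .. n_levels - 1`.
#' @return named list of five matrices (`asm`, `contrast`, `dissimilarity`,
#'   `entropy`, `homogeneity`) the size of `image`.
#' @export
texture_maps <- function(image, kernel_size, n_levels = 32L,
                         offsets = glcm_offsets(), symmetric = TRUE,
                         quantized = FALSE) {
  if (kernel_size %% 2 == 0L) stop("kernel_size must be odd")
  if (kernel_size < 3L) stop("kernel_size must be >= 3")
  lv <- if (quantized) image else
    quantize_grey(image, bits_out = as.integer(round(log2(n_levels))))
  storage.mode(lv) <- "integer"
  if (any(lv < 0 | lv >= n_levels)) stop("levels out of range")
  glcm_texture_maps_cpp(lv, as.integer(kernel_size), as.integer(n_levels),
                        offsets, symmetric)
}

#' Sixteen-value object feature vector
#'
#' Mean and population SD of each RGB band over the object's pixels, plus
#' mean and population SD of each of the five texture maps over the
#' object's pixels that carry valid texture values (outside the kernel
#' margin). Background (masked-out) pixels never enter the statistics.
#'
#' @param object_mask logical matrix selecting the object's pixels.
#' @param rgb_bands rows x cols x 3 array aligned with the mask.
#' @param tex_maps list of five texture maps from [texture_maps()].
#' @return a 1-row tibble with 16 feature columns
#'   (`R_mean, R_sd, ..., asm_mean, asm_sd, ...`).
#' @export
object_feature_vector <- function(object_mask, rgb_bands, tex_maps) {
  stopifnot(is.logical(object_mask), sum(object_mask) >= 1L)
  valid <- object_mask & !is.na(tex_maps[[1]])
  if (!any(valid)) {
    stop("object has no pixels with valid texture values ",
         "(entirely inside the kernel margin)")
  }
  out <- list()
  for (b in 1:3) {
    v <- rgb_bands[, , b][object_mask]
    out[[paste0(c("R", "G", "B")[b], "_mean")]] <- mean(v)
    out[[paste0(c("R", "G", "B")[b], "_sd")]] <- sd_pop(v)
  }
  for (nm in names(tex_maps)) {
    v <- tex_maps[[nm]][valid]
    out[[paste0(nm, "_mean")]] <- mean(v)
    out[[paste0(nm, "_sd")]] <- sd_pop(v)
  }
  tibble::as_tibble(out)
}

#' Object feature table for a segmented scene
#'
#' Computes whole-scene texture maps of the greyscale orthomosaic at one
#' kernel size, then assembles the 16-value feature vector for every
#' segment (optionally restricted to a subset of segment ids), attaching
#' labels when given.
#'
#' @param ortho 3-band [raster_grid].
#' @param segmap a [segment_map].
#' @param kernel_size GLCM kernel size (odd).
#' @param labels optional named/numeric vector of class labels per segment
#'   id.
#' @param ids segment ids to include (default: all).
#' @param n_levels,offsets,symmetric co-occurrence convention.
#' @return tibble: `id`, 16 features, `label` (NA when unknown),
#'   `kernel_size`; segments without valid texture pixels are dropped with
#'   a warning.
#' @export
object_feature_table <- function(ortho, segmap, kernel_size = 51L,
                                 labels = NULL, ids = NULL, n_levels = 32L,
                                 offsets = glcm_offsets(), symmetric = TRUE) {
  grey <- to_grey(ortho$values)
  tm <- texture_maps(grey, kernel_size, n_levels, offsets, symmetric)
  lab_grid <- segmap$labels
  if (is.null(ids)) ids <- sort(unique(as.vector(lab_grid)))
  rows <- list()
  dropped <- integer(0)
  for (id in ids) {
    mask <- lab_grid == id
    row <- tryCatch(object_feature_vector(mask, ortho$values, tm),
                    error = function(e) NULL)
    if (is.null(row)) { dropped <- c(dropped, id); next }
    row$id <- id
    rows[[length(rows) + 1L]] <- row
  }
  if (length(dropped)) {
    warning("dropped ", length(dropped),
            " segment(s) without valid texture pixels: ",
            paste(utils::head(dropped, 10), collapse = ", "))
  }
  out <- do.call(rbind, rows)
  out <- out[, c("id", setdiff(names(out), "id"))]
  out$label <- if (is.null(labels)) NA_integer_ else
    as.integer(labels[as.character(out$id)])
  out$kernel_size <- as.integer(kernel_size)
  out
}

#' GLCM kernel-size sweep with SVM validation
#'
#' For each candidate kernel size, recomputes the object features, runs the
#' radial-kernel SVM grid search over the fold plan, and records the best
#' mean validation accuracy. Returns the size with the highest accuracy
#' (ties resolved toward the smallest size).
#'
#' @param ortho,segmap,labels scene inputs as in [object_feature_table()].
#' @param plan a [make_fold_plan()] fold plan over the labelled ids.
#' @param sizes candidate odd kernel sizes.
#' @param gamma_grid,cost_grid SVM grids, see [train_svm_grid()].
#' @param ... passed to [object_feature_table()].
#' @return list with `best_size` and `table` (one ascending row per size:
#'   `kernel_size`, `val_accuracy`, best `gamma`, `cost`).
#' @export
kernel_sweep_select <- function(ortho, segmap, labels, plan,
                                sizes = c(3L, 11L, 19L, 27L, 35L, 43L, 51L, 59L),
                                gamma_grid = 10^(-1:-5),
                                cost_grid = 10^(0:5), ...) {
  lab <- labels[!is.na(labels)]
  if (length(unique(lab)) < 2L) {
    stop("kernel sweep needs at least two classes")
  }
  sizes <- sort(as.integer(sizes))
  rows <- lapply(sizes, function(k) {
    ft <- object_feature_table(ortho, segmap, kernel_size = k,
                               labels = labels, ids = as.integer(names(labels)),
                               ...)
    fit <- train_svm_grid(ft, plan, gamma_grid = gamma_grid,
                          cost_grid = cost_grid)
    tibble::tibble(kernel_size = k,
                   val_accuracy = mean(fit$rotations$val_accuracy),
                   gamma = fit$rotations$gamma[1],
                   cost = fit$rotations$cost[1])
  })
  tab <- do.call(rbind, rows)
  best <- tab$kernel_size[which.max(tab$val_accuracy)]
  list(best_size = best, table = tab)
}
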