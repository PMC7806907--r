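#' Grad-CAM attention map
#'
#' Class-activation mapping from gradient-weighted convolutional features:
#' the gradient of the target-class logit with respect to the chosen
#' layer's feature maps is averaged spatially into one weight per channel;
#' the attention map is the rectified (ReLU) weighted sum of the feature
#' maps, bilinearly upsampled to the input patch size. Nonnegative by
#' construction.
#'
#' @param model a trained [tree_cnn][cnn_new()].
#' @param patch input RGB patch (values 0..255 or 0..1).
#' @param target_class class index whose evidence is mapped.
#' @param layer spatial layer name: `"conv1"`, `"conv2"` or `"conv3"` (the
#'   last convolutional stage, the default, mirrors using the final
#'   convolutional block of a deep backbone).
#' @return an object of class `attention_map`: `values` (patch-sized
#'   nonnegative matrix), `coarse` (layer-resolution map), `target_class`,
#'   `layer`.
#' @export
grad_cam <- function(model, patch, target_class, layer = "conv3") {
  if (!layer %in% c("conv1", "conv2", "conv3")) {
    stop("layer without spatial feature maps: ", layer)
  }
  x <- normalize_patch(patch)
  cache <- cnn_forward(model, x)
  dlog <- matrix(0, model$n_classes, 1)
  dlog[target_class, 1] <- 1
  grads <- cnn_backward(model, cache, dlog)
  acts <- switch(layer, conv1 = cache$r1$out, conv2 = cache$r2$out,
                 conv3 = cache$r3$out)
  # gradient w.r.t. the rectified activations of the chosen layer
  gr <- switch(layer,
    conv3 = gap_backward(crossprod(model$params$Wf, dlog), cache$gap),
    conv2 = , conv1 = {
      # recompute by chaining from the stored per-layer input gradients
      g3 <- relu_backward(gap_backward(crossprod(model$params$Wf, dlog),
                                       cache$gap), cache$r3)
      b3 <- conv_backward(g3, cache$c3, model$params$W3)
      g2in <- maxpool_backward(b3$dx, cache$p2)
      if (layer == "conv2") g2in else {
        g2 <- relu_backward(g2in, cache$r2)
        b2 <- conv_backward(g2, cache$c2, model$params$W2)
        maxpool_backward(b2$dx, cache$p1)
      }
    })
  nch <- dim(acts)[3]
  w <- vapply(seq_len(nch), function(k) mean(gr[, , k, 1]), 0)
  cam <- matrix(0, dim(acts)[1], dim(acts)[2])
  for (k in seq_len(nch)) cam <- cam + w[k] * acts[, , k, 1]
  cam <- pmax(cam, 0)
  d <- if (is.matrix(patch)) dim(patch) else dim(patch)[1:2]
  up <- resample_bilinear(cam, d[1], d[2])
  structure(list(values = up, coarse = cam,
                 target_class = as.integer(target_class), layer = layer),
            class = "attention_map")
}

#' Guided backpropagation
#'
#' Gradient of the target-class logit with respect to the input pixels,
#' where every rectifier's backward pass zeroes both gradients at inactive
#' units (forward activation <= 0) and negative upstream gradients. The
#' result highlights fine image structure that increases the class score.
#'
#' @param model a trained [tree_cnn][cnn_new()].
#' @param patch input RGB patch.
#' @param target_class class index.
#' @return gradient array with the shape of the input patch.
#' @export
guided_backprop <- function(model, patch, target_class) {
  x <- normalize_patch(patch)
  cache <- cnn_forward(model, x)
  dlog <- matrix(0, model$n_classes, 1)
  dlog[target_class, 1] <- 1
  grads <- cnn_backward(model, cache, dlog, guided = TRUE)
  g <- grads$input
  out <- array(g, dim(g)[1:3])
  if (is.matrix(patch)) out[, , 1] else out
}

#' Guided Grad-CAM
#'
#' Elementwise product of the (nonnegative, class-localising) Grad-CAM map
#' and the (fine-grained) guided-backpropagation gradient: zero wherever
#' the coarse map is zero, detailed inside the highlighted regions.
#'
#' @param cam an [attention_map][grad_cam()] (or patch-sized matrix).
#' @param gbp a [guided_backprop()] gradient (matrix or 3-band array; bands
#'   are averaged to one channel first).
#' @return an `attention_map` whose `values` may carry either sign.
#' @export
guided_grad_cam <- function(cam, gbp) {
  cam_v <- if (inherits(cam, "attention_map")) cam$values else cam
  g <- if (length(dim(gbp)) == 3L) apply(gbp, c(1, 2), mean) else gbp
  if (!all(dim(cam_v) == dim(g))) {
    stop("attention map and gradient shapes differ: ",
         paste(dim(cam_v), collapse = "x"), " vs ",
         paste(dim(g), collapse = "x"))
  }
  structure(list(values = cam_v * g, coarse = cam_v,
                 target_class = if (inherits(cam, "attention_map"))
                   cam$target_class else NA_integer_,
                 layer = if (inherits(cam, "attention_map")) cam$layer else
                   NA_character_),
            class = "attention_map")
}

#' Overlay an attention map on the greyscale patch
#'
#' Pure visualization: the patch is converted to greyscale and the
#' attention values, scaled so the maximum absolute attention reaches full
#' heat intensity, are blended into the red channel.
#'
#' @param patch RGB patch (0..255 or 0..1).
#' @param attention an `attention_map` or patch-sized matrix.
#' @param alpha maximum heat opacity.
#' @return rows x cols x 3 array in `[0, 1]` (write with [save_png()]).
#' @export
render_overlay <- function(patch, attention, alpha = 0.7) {
  att <- if (inherits(attention, "attention_map")) attention$values else
    attention
  p <- patch
  if (max(p, na.rm = TRUE) > 1.5) p <- p / 255
  grey <- if (is.matrix(p)) p else
    0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3]
  stopifnot(all(dim(att) == dim(grey)))
  m <- max(abs(att))
  heat <- if (m > 0) abs(att) / m else att * 0
  out <- array(0, c(dim(grey), 3))
  out[, , 1] <- pmin(grey * (1 - alpha * heat) + alpha * heat, 1)
  out[, , 2] <- grey * (1 - alpha * heat)
  out[, , 3] <- grey * (1 - alpha * heat)
  out
}

#' Write an image array to PNG
#'
#' @param img matrix or rows x cols x 3 array in `[0, 1]`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Fraction of attention mass inside a mask
#'
#' Total absolute attention inside the mask divided by total absolute
#' attention, a sanity measure of whether the explanation concentrates on
#' the object (e.g. the crown) rather than the background.
#'
#' @param attention `attention_map` or matrix.
#' @param mask logical matrix of the same shape.
#' @return fraction in `[0, 1]` (`NA` when the map is all zero).
#' @export
attention_inside_fraction <- function(attention, mask) {
  v <- if (inherits(attention, "attention_map")) attention$values else
    attention
  stopifnot(all(dim(v) == dim(mask)))
  tot <- sum(abs(v))
  if (tot == 0) return(NA_real_)
  sum(abs(v)[mask]) / tot
}
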