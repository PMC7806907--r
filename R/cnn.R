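# Compact convolutional network with hand-written forward/backward passes.
# Explicit gradients (rather than an external autograd) are what make
# Grad-CAM, guided backpropagation and the finite-difference gradient
# checks possible with no heavyweight dependency.
#
# Architecture (desk-scale default):
#   stem:  fixed average pooling (factor `stem_pool`, no parameters)
#   conv1: 3x3, pad 1, `channels[1]` maps + ReLU, then 2x2 max pool
#   conv2: 3x3, pad 1, `channels[2]` maps + ReLU, then 2x2 max pool
#   conv3: 3x3, pad 1, `channels[3]` maps + ReLU   <- Grad-CAM target layer
#   head:  global average pooling + dense layer (one logit per class)

#' Create an untrained compact CNN
#'
#' @param n_classes output layer width (number of classes).
#' @param cfg a [train_config()]; `patch_size`, `stem_pool` and `channels`
#'   define the architecture.
#' @param in_channels input bands (3 for RGB patches).
#' @param seed weight-initialization seed (He-scaled Gaussian).
#' @return an object of class `tree_cnn`.
#' @export
cnn_new <- function(n_classes = 7L, cfg = train_config(), in_channels = 3L,
                    seed = 1L) {
  set.seed(as.integer(seed))
  ch <- c(in_channels, cfg$channels)
  he <- function(fan_in, nrow, ncol) {
    matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
  }
  params <- list()
  for (l in 1:3) {
    params[[paste0("W", l)]] <- he(9 * ch[l], ch[l + 1], 9 * ch[l])
    params[[paste0("b", l)]] <- numeric(ch[l + 1])
  }
  params$Wf <- he(ch[4], n_classes, ch[4])
  params$bf <- numeric(n_classes)
  structure(list(params = params, n_classes = as.integer(n_classes),
                 cfg = cfg, in_channels = as.integer(in_channels)),
            class = "tree_cnn")
}

# --- primitive layers (batched on h x w x c x n arrays) -----------------

.idx_cache <- new.env(parent = emptyenv())

im2col_idx <- function(h, w, c) {
  key <- paste(h, w, c)
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  hp <- h + 2L; wp <- w + 2L
  kr <- rep(0:2, times = 3)
  kc <- rep(0:2, each = 3)
  # rows: (kernel position x channel), cols: output pixels, column-major
  out <- matrix(0L, 9L * c, h * w)
  pix <- 0L
  for (ccc in seq_len(w)) {
    for (r in seq_len(h)) {
      pix <- pix + 1L
      p00 <- (ccc - 1L) * hp + r  # padded linear index of kernel corner
      k9 <- p00 + kr + hp * kc
      out[, pix] <- rep(k9, times = c) + rep((0:(c - 1L)) * hp * wp, each = 9L)
    }
  }
  .idx_cache[[key]] <- out
  out
}

pad_batch <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1] + 2L, d[2] + 2L, d[3], d[4]))
  out[2:(d[1] + 1L), 2:(d[2] + 1L), , ] <- x
  out
}

conv_forward <- function(x, W, b, idx) {
  d <- dim(x)
  xp <- pad_batch(x)
  npad <- prod(dim(xp)[1:3])
  n <- d[4]
  gather <- rep(as.vector(idx), times = n) +
    rep(npad * (0:(n - 1L)), each = length(idx))
  X <- matrix(xp[gather], nrow(idx), ncol(idx) * n)
  Z <- W %*% X + b
  out <- array(0, c(d[1], d[2], nrow(W), n))
  for (i in seq_len(n)) {
    cols <- ((i - 1L) * d[1] * d[2] + 1L):(i * d[1] * d[2])
    out[, , , i] <- array(t(Z[, cols, drop = FALSE]),
                          c(d[1], d[2], nrow(W)))
  }
  list(out = out, X = X, dims = d, npad = npad, gather = gather)
}

conv_backward <- function(dout, cache, W) {
  d <- cache$dims
  n <- d[4]
  hw <- d[1] * d[2]
  dZ <- matrix(0, nrow(W), hw * n)
  for (i in seq_len(n)) {
    cols <- ((i - 1L) * hw + 1L):(i * hw)
    dZ[, cols] <- t(matrix(dout[, , , i], hw, nrow(W)))
  }
  dW <- dZ %*% t(cache$X)
  db <- rowSums(dZ)
  dX <- crossprod(W, dZ)
  acc <- rowsum(as.vector(dX), cache$gather)
  dxp <- numeric(cache$npad * n)
  dxp[as.integer(rownames(acc))] <- acc[, 1]
  dxp <- array(dxp, c(d[1] + 2L, d[2] + 2L, d[3], n))
  dx <- dxp[2:(d[1] + 1L), 2:(d[2] + 1L), , , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

relu_forward <- function(x) list(out = pmax(x, 0), mask = x > 0)
relu_backward <- function(dout, cache) dout * cache$mask

maxpool_forward <- function(x) {
  d <- dim(x)
  h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  a <- x[seq(1, 2 * h2, 2), seq(1, 2 * w2, 2), , , drop = FALSE]
  b <- x[seq(2, 2 * h2, 2), seq(1, 2 * w2, 2), , , drop = FALSE]
  cc <- x[seq(1, 2 * h2, 2), seq(2, 2 * w2, 2), , , drop = FALSE]
  dd <- x[seq(2, 2 * h2, 2), seq(2, 2 * w2, 2), , , drop = FALSE]
  out <- pmax(a, b, cc, dd)
  list(out = out, which = list(a = out == a, b = out == b & out != a,
                               cc = out == cc & out != a & out != b,
                               dd = out == dd & out != a & out != b &
                                 out != cc),
       dims = d)
}

maxpool_backward <- function(dout, cache) {
  d <- cache$dims
  h2 <- dim(dout)[1]; w2 <- dim(dout)[2]
  dx <- array(0, d)
  dx[seq(1, 2 * h2, 2), seq(1, 2 * w2, 2), , ] <- dout * cache$which$a
  dx[seq(2, 2 * h2, 2), seq(1, 2 * w2, 2), , ] <-
    dx[seq(2, 2 * h2, 2), seq(1, 2 * w2, 2), , , drop = FALSE] +
    dout * cache$which$b
  dx[seq(1, 2 * h2, 2), seq(2, 2 * w2, 2), , ] <-
    dx[seq(1, 2 * h2, 2), seq(2, 2 * w2, 2), , , drop = FALSE] +
    dout * cache$which$cc
  dx[seq(2, 2 * h2, 2), seq(2, 2 * w2, 2), , ] <-
    dx[seq(2, 2 * h2, 2), seq(2, 2 * w2, 2), , , drop = FALSE] +
    dout * cache$which$dd
  dx
}

stem_forward <- function(x, s) {
  if (s <= 1L) return(x)
  d <- dim(x)
  h2 <- d[1] %/% s; w2 <- d[2] %/% s
  y <- array(x, c(s, h2, d[2], d[3], d[4]))
  y <- colMeans(y)                     # (h2, w, c, n)
  y <- aperm(y, c(2, 1, 3, 4))         # (w, h2, c, n)
  y <- array(y, c(s, w2, h2, d[3], d[4]))
  y <- colMeans(y)                     # (w2, h2, c, n)
  aperm(y, c(2, 1, 3, 4))
}

stem_backward <- function(dout, s, dims_in) {
  if (s <= 1L) return(dout)
  d <- dim(dout)
  g <- dout / (s * s)
  big <- array(0, dims_in)
  # upsample by block replication
  ri <- rep(seq_len(d[1]), each = s)
  ci <- rep(seq_len(d[2]), each = s)
  big[] <- g[ri, ci, , , drop = FALSE]
  big
}

gap_forward <- function(x) {
  d <- dim(x)
  hw <- d[1] * d[2]
  feat <- matrix(colMeans(matrix(x, hw, d[3] * d[4])), d[3], d[4])
  list(out = feat, dims = d)
}

gap_backward <- function(dfeat, cache) {
  d <- cache$dims
  hw <- d[1] * d[2]
  array(rep(as.vector(dfeat), each = hw) / hw, d)
}

# Full forward pass; keeps every intermediate needed for the backward pass
# and for attention mapping.
cnn_forward <- function(model, x, from_stem = TRUE) {
  p <- model$params
  cfg <- model$cfg
  if (length(dim(x)) == 3L) x <- array(x, c(dim(x), 1L))
  cache <- list(input = x)
  h <- if (from_stem) stem_forward(x, cfg$stem_pool) else x
  cache$stem_out <- h
  cache$idx1 <- im2col_idx(dim(h)[1], dim(h)[2], dim(h)[3])
  cache$c1 <- conv_forward(h, p$W1, p$b1, cache$idx1)
  cache$r1 <- relu_forward(cache$c1$out)
  cache$p1 <- maxpool_forward(cache$r1$out)
  h <- cache$p1$out
  cache$idx2 <- im2col_idx(dim(h)[1], dim(h)[2], dim(h)[3])
  cache$c2 <- conv_forward(h, p$W2, p$b2, cache$idx2)
  cache$r2 <- relu_forward(cache$c2$out)
  cache$p2 <- maxpool_forward(cache$r2$out)
  h <- cache$p2$out
  cache$idx3 <- im2col_idx(dim(h)[1], dim(h)[2], dim(h)[3])
  cache$c3 <- conv_forward(h, p$W3, p$b3, cache$idx3)
  cache$r3 <- relu_forward(cache$c3$out)
  cache$gap <- gap_forward(cache$r3$out)
  logits <- p$Wf %*% cache$gap$out + p$bf
  cache$logits <- logits
  cache
}

# Backward from a gradient on the logits; `guided` switches every ReLU to
# the guided-backpropagation rule (zero negative upstream gradients as well
# as gradients at inactive units).
cnn_backward <- function(model, cache, dlogits, guided = FALSE,
                         from_stem = TRUE) {
  p <- model$params
  relu_bwd <- function(dout, rc) {
    g <- relu_backward(dout, rc)
    if (guided) g <- g * (g > 0)
    g
  }
  grads <- list()
  grads$Wf <- dlogits %*% t(cache$gap$out)
  grads$bf <- rowSums(dlogits)
  dfeat <- crossprod(p$Wf, dlogits)
  dh <- gap_backward(dfeat, cache$gap)
  dh <- relu_bwd(dh, cache$r3)
  bk <- conv_backward(dh, cache$c3, p$W3)
  grads$W3 <- bk$dW; grads$b3 <- bk$db
  grads$conv3_input <- bk$dx
  dh <- maxpool_backward(bk$dx, cache$p2)
  dh <- relu_bwd(dh, cache$r2)
  bk <- conv_backward(dh, cache$c2, p$W2)
  grads$W2 <- bk$dW; grads$b2 <- bk$db
  dh <- maxpool_backward(bk$dx, cache$p1)
  dh <- relu_bwd(dh, cache$r1)
  bk <- conv_backward(dh, cache$c1, p$W1)
  grads$W1 <- bk$dW; grads$b1 <- bk$db
  grads$stem_out <- bk$dx
  grads$input <- if (from_stem) {
    stem_backward(bk$dx, model$cfg$stem_pool, dim(cache$input))
  } else bk$dx
  grads
}

softmax <- function(logits) {
  z <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

#' Predict class labels with a trained CNN
#'
#' @param model a [tree_cnn][cnn_new()].
#' @param patches list of `patch_size` RGB patches (values 0..255 or 0..1).
#' @return integer vector of predicted labels.
#' @export
predict_cnn <- function(model, patches) {
  vapply(patches, function(pt) {
    x <- normalize_patch(pt)
    cache <- cnn_forward(model, x)
    which.max(cache$logits[, 1])
  }, 0L)
}

normalize_patch <- function(pt) {
  if (is.matrix(pt)) pt <- array(pt, c(dim(pt), 1L))
  if (max(pt, na.rm = TRUE) > 1.5) pt <- pt / 255
  pt - 0.5
}

#' Train the compact CNN over the fold plan
#'
#' For each of the four rotations, training images are augmented eightfold
#' (dihedral transforms, training folds only — augmentation strictly after
#' the split), mini-batch SGD with momentum minimizes the softmax
#' cross-entropy, and the epoch with the best validation accuracy supplies
#' the weights used to predict the rotation's test items. Test predictions
#' are pooled across rotations. Deterministic for fixed seeds.
#'
#' @param patches named list (by item id) of 224 x 224 x 3 patches used for
#'   training (train-mode crops), or a list with elements `train` and
#'   `eval` holding separate patch sets for the two roles.
#' @param labels named integer vector of class labels by item id.
#' @param plan a [make_fold_plan()] over the item ids.
#' @param cfg a [train_config()].
#' @param n_classes output layer width.
#' @return list of class `cnn_result`: `models` (one per rotation),
#'   `predictions` (tibble: id, truth, prediction, rotation), `history`.
#' @export
train_cnn <- function(patches, labels, plan, cfg = train_config(),
                      n_classes = 7L) {
  stopifnot(inherits(plan, "fold_plan"))
  if (!is.null(patches$train) && !is.null(patches$eval)) {
    p_train <- patches$train; p_eval <- patches$eval
  } else {
    p_train <- patches; p_eval <- patches
  }
  ids <- names(p_train)
  labels <- labels[ids]
  models <- list(); preds <- list(); history <- list()
  for (r in seq_along(plan$rotations)) {
    rot <- plan$rotations[[r]]
    tr_ids <- as.character(rot$train)
    if (!all(unique(labels) %in% labels[tr_ids])) {
      missing <- setdiff(unique(labels), labels[tr_ids])
      stop("rotation ", r, ": class(es) ", paste(missing, collapse = ", "),
           " absent from the training folds")
    }
    # augmentation strictly after the split: training items only
    xs <- list(); ys <- integer(0)
    for (id in tr_ids) {
      imgs <- if (cfg$augment) augment_dihedral(p_train[[id]]) else
        list(p_train[[id]])
      for (im in imgs) {
        xs[[length(xs) + 1L]] <- normalize_patch(im)
        ys <- c(ys, labels[[id]])
      }
    }
    set.seed(cfg$seed * 1000L + r)
    model <- cnn_new(n_classes, cfg, seed = cfg$seed * 1000L + r)
    # precompute the (parameter-free) stem once per training patch
    xs_stem <- lapply(xs, function(x)
      stem_forward(array(x, c(dim(x), 1L)), cfg$stem_pool))
    vel <- lapply(model$params, function(p) p * 0)
    n_tr <- length(xs_stem)
    best <- list(acc = -1, params = model$params, epoch = 0L)
    va_ids <- as.character(rot$validation)
    hist_r <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n_tr)
      for (start in seq(1, n_tr, by = cfg$batch_size)) {
        bi <- ord[start:min(start + cfg$batch_size - 1L, n_tr)]
        d1 <- dim(xs_stem[[1]])
        xb <- array(0, c(d1[1], d1[2], d1[3], length(bi)))
        for (k in seq_along(bi)) xb[, , , k] <- xs_stem[[bi[k]]][, , , 1]
        yb <- ys[bi]
        cache <- cnn_forward(model, xb, from_stem = FALSE)
        pr <- softmax(cache$logits)
        dlog <- pr
        dlog[cbind(yb, seq_along(bi))] <-
          dlog[cbind(yb, seq_along(bi))] - 1
        dlog <- dlog / length(bi)
        g <- cnn_backward(model, cache, dlog, from_stem = FALSE)
        for (nm in names(model$params)) {
          vel[[nm]] <- 0.9 * vel[[nm]] - cfg$lr * g[[nm]]
          model$params[[nm]] <- model$params[[nm]] + vel[[nm]]
        }
      }
      va_pred <- predict_cnn(model, p_eval[va_ids])
      acc <- mean(va_pred == labels[va_ids])
      hist_r[ep] <- acc
      if (acc > best$acc) best <- list(acc = acc, params = model$params,
                                       epoch = ep)
    }
    model$params <- best$params
    te_ids <- as.character(rot$test)
    te_pred <- predict_cnn(model, p_eval[te_ids])
    models[[r]] <- model
    preds[[r]] <- tibble::tibble(id = te_ids, truth = labels[te_ids],
                                 prediction = te_pred, rotation = r)
    history[[r]] <- hist_r
  }
  structure(list(models = models, predictions = do.call(rbind, preds),
                 history = history),
            class = "cnn_result")
}
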