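#' Four-fold rotation plan
#'
#' Randomly divides the items evenly into four subsets, then builds four
#' rotations: in each, two subsets train, one validates, one tests, with
#' roles interchanged successively so every subset serves as the test set
#' exactly once. When `labels` are supplied the split is stratified by
#' class so each subset carries every class (small, imbalanced object sets
#' otherwise risk class-free training folds).
#'
#' @param item_ids vector of item identifiers (>= 4 items).
#' @param seed integer seed.
#' @param labels optional class labels aligned with `item_ids` for
#'   stratification.
#' @return an object of class `fold_plan`: `subsets` (list of 4 id
#'   vectors), `rotations` (list of 4 lists with `train`, `validation`,
#'   `test` id vectors), `seed`.
#' @export
make_fold_plan <- function(item_ids, seed = 1L, labels = NULL) {
  n <- length(item_ids)
  if (n < 4L) stop("need at least 4 items to build 4 folds")
  set.seed(as.integer(seed))
  assign_fold <- function(ids) {
    ids <- sample(ids)
    split(ids, rep_len(1:4, length(ids)))
  }
  if (is.null(labels)) {
    subsets <- assign_fold(item_ids)
  } else {
    stopifnot(length(labels) == n)
    subsets <- list(c(), c(), c(), c())
    offset <- 0L
    for (cl in unique(labels)) {
      ids <- sample(item_ids[labels == cl])
      # rotate the starting fold per class so subset sizes stay balanced
      fold <- (offset + seq_along(ids) - 1L) %% 4L + 1L
      for (k in 1:4) subsets[[k]] <- c(subsets[[k]], ids[fold == k])
      offset <- (offset + length(ids)) %% 4L
    }
  }
  subsets <- lapply(1:4, function(k) subsets[[k]])
  rotations <- lapply(1:4, function(r) {
    test <- r
    val <- r %% 4L + 1L
    train <- setdiff(1:4, c(test, val))
    list(train = unlist(subsets[train], use.names = FALSE),
         validation = subsets[[val]], test = subsets[[test]])
  })
  structure(list(subsets = subsets, rotations = rotations,
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' Eightfold dihedral augmentation
#'
#' The 8 transforms of the dihedral group of the square: rotations by 0,
#' 90, 180 and 270 degrees, each with and without a horizontal flip. The
#' identity (original image) is included.
#'
#' @param image matrix or rows x cols x bands array.
#' @return list of 8 images.
#' @export
augment_dihedral <- function(image) {
  rot90m <- function(m) t(m[nrow(m):1, , drop = FALSE])  # 90 deg clockwise
  fliph <- function(m) m[, ncol(m):1, drop = FALSE]
  apply_bands <- function(x, f) {
    if (is.matrix(x)) return(f(x))
    slices <- lapply(seq_len(dim(x)[3]), function(b) f(x[, , b]))
    array(unlist(slices), c(dim(slices[[1]]), dim(x)[3]))
  }
  out <- vector("list", 8L)
  cur <- image
  for (r in 1:4) {
    out[[2 * r - 1]] <- cur
    out[[2 * r]] <- apply_bands(cur, fliph)
    cur <- apply_bands(cur, rot90m)
  }
  out
}

#' Training configuration for the CNN
#'
#' @param patch_size input patch side after cropping (pixels).
#' @param resize_size shorter-side length for evaluation resizing.
#' @param augment use eightfold dihedral augmentation on training folds.
#' @param lr,batch_size,epochs optimizer settings of the compact CNN.
#' @param stem_pool fixed average-pooling factor of the network stem.
#' @param channels channel widths of the three convolution stages.
#' @param seed training seed.
#' @return an object of class `train_config`.
#' @export
train_config <- function(patch_size = 224L, resize_size = 256L,
                         augment = TRUE, lr = 0.01, batch_size = 16L,
                         epochs = 30L, stem_pool = 8L,
                         channels = c(16L, 32L, 32L), seed = 1L) {
  stopifnot(patch_size <= resize_size, patch_size %% stem_pool == 0)
  structure(list(patch_size = as.integer(patch_size),
                 resize_size = as.integer(resize_size),
                 augment = isTRUE(augment), lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), stem_pool = as.integer(stem_pool),
                 channels = as.integer(channels), seed = as.integer(seed)),
            class = "train_config")
}

#' Crop and resize an image to a network input patch
#'
#' Training mode applies a seeded random resized crop: a sub-window of
#' random area (8-100% of the image) and aspect ratio (3:4 to 4:3) is cut
#' and resized to `patch_size`. Evaluation mode resizes the shorter side to
#' `resize_size` and takes the central `patch_size` crop. Exactly one patch
#' is produced per input; small images are upscaled as needed.
#'
#' @param image matrix or rows x cols x bands array.
#' @param mode `"train"` or `"eval"`.
#' @param cfg a [train_config].
#' @param seed seed for the random crop (train mode).
#' @return `patch_size x patch_size (x bands)` array.
#' @export
preprocess_patch <- function(image, mode = c("train", "eval"),
                             cfg = train_config(), seed = 1L) {
  mode <- match.arg(mode)
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  nr <- dim(image)[1]; nc <- dim(image)[2]
  if (nr == 0L || nc == 0L) stop("empty image")
  ps <- cfg$patch_size
  if (mode == "train") {
    set.seed(as.integer(seed))
    area <- nr * nc
    crop <- NULL
    for (i in 1:10) {
      target <- stats::runif(1, 0.08, 1.0) * area
      ar <- exp(stats::runif(1, log(3 / 4), log(4 / 3)))
      ch <- round(sqrt(target / ar))
      cw <- round(sqrt(target * ar))
      if (ch >= 1 && cw >= 1 && ch <= nr && cw <= nc) {
        r0 <- sample.int(nr - ch + 1L, 1L)
        c0 <- sample.int(nc - cw + 1L, 1L)
        crop <- image[r0:(r0 + ch - 1L), c0:(c0 + cw - 1L), , drop = FALSE]
        break
      }
    }
    if (is.null(crop)) crop <- image  # fallback: whole image
    out <- resample_bilinear(crop, ps, ps)
  } else {
    scale <- cfg$resize_size / min(nr, nc)
    rs <- resample_bilinear(image, max(ps, round(nr * scale)),
                            max(ps, round(nc * scale)))
    r0 <- floor((dim(rs)[1] - ps) / 2) + 1L
    c0 <- floor((dim(rs)[2] - ps) / 2) + 1L
    out <- rs[r0:(r0 + ps - 1L), c0:(c0 + ps - 1L), , drop = FALSE]
  }
  if (dim(out)[3] == 1L) out[, , 1] else out
}

#' Radial-kernel SVM with parameter grid search over the fold plan
#'
#' For each rotation of the plan, features are z-scored with the training
#' fold's statistics, an RBF-kernel SVM is fitted at every `(gamma, cost)`
#' pair of the decade grids, the pair with the best validation accuracy is
#' kept (ties keep the first pair in grid order), and the selected model
#' predicts the rotation's test items. Test predictions are pooled across
#' rotations.
#'
#' @param features an [object_feature_table()] (columns `id`, 16 features,
#'   `label`).
#' @param plan a [make_fold_plan()] over the feature `id`s.
#' @param gamma_grid,cost_grid numeric grids (defaults: decade steps over
#'   `10^-1 .. 10^-5` and `1 .. 10^5`).
#' @return list of class `svm_result`: `rotations` (tibble: rotation, gamma,
#'   cost, val_accuracy), `models`, `predictions` (tibble: id, truth,
#'   prediction, rotation), `grid_size`.
#' @export
train_svm_grid <- function(features, plan, gamma_grid = 10^(-1:-5),
                           cost_grid = 10^(0:5)) {
  stopifnot(inherits(plan, "fold_plan"))
  feat_cols <- setdiff(names(features), c("id", "label", "kernel_size"))
  lab <- features$label
  if (length(unique(lab[!is.na(lab)])) < 2L) {
    stop("SVM training needs at least two classes")
  }
  grid <- expand.grid(gamma = gamma_grid, cost = cost_grid,
                      KEEP.OUT.ATTRS = FALSE)
  rot_rows <- list(); models <- list(); preds <- list()
  for (r in seq_along(plan$rotations)) {
    rot <- plan$rotations[[r]]
    tr <- features[features$id %in% rot$train, ]
    va <- features[features$id %in% rot$validation, ]
    te <- features[features$id %in% rot$test, ]
    if (length(unique(tr$label)) < 2L) {
      stop("rotation ", r, ": training fold has a single class")
    }
    mu <- vapply(tr[feat_cols], mean, 0)
    sg <- vapply(tr[feat_cols], stats::sd, 0)
    sg[sg == 0 | is.na(sg)] <- 1
    zs <- function(df) {
      m <- as.matrix(df[feat_cols])
      sweep(sweep(m, 2, mu), 2, sg, "/")
    }
    Xtr <- zs(tr); Xva <- zs(va); Xte <- zs(te)
    ytr <- factor(tr$label)
    yva <- as.character(va$label)   # classes unseen in training stay wrong
    best <- NULL
    for (g in seq_len(nrow(grid))) {
      fit <- e1071::svm(Xtr, ytr, kernel = "radial",
                        gamma = grid$gamma[g], cost = grid$cost[g],
                        scale = FALSE)
      acc <- mean(as.character(stats::predict(fit, Xva)) == yva)
      if (is.null(best) || acc > best$acc) {
        best <- list(acc = acc, gamma = grid$gamma[g], cost = grid$cost[g],
                     fit = fit)
      }
    }
    pr <- as.integer(as.character(stats::predict(best$fit, Xte)))
    rot_rows[[r]] <- tibble::tibble(rotation = r, gamma = best$gamma,
                                    cost = best$cost,
                                    val_accuracy = best$acc)
    models[[r]] <- best$fit
    preds[[r]] <- tibble::tibble(id = te$id, truth = te$label,
                                 prediction = pr, rotation = r)
  }
  structure(list(rotations = do.call(rbind, rot_rows), models = models,
                 predictions = do.call(rbind, preds),
                 grid_size = nrow(grid)),
            class = "svm_result")
}

#' Confusion matrix and agreement metrics
#'
#' Pools predictions (typically all rotations' test sets) into one
#' confusion matrix with ground truth on rows and model prediction on
#' columns, and derives overall accuracy (`trace / total`), Cohen's Kappa
#' (`(p_o - p_e) / (1 - p_e)` with expected agreement from the row/column
#' marginals), per-class F1 (harmonic mean of precision and recall; 0 when
#' undefined for a class that occurs) and macro F1 (unweighted mean of
#' per-class F1 over classes present in truth or prediction).
#'
#' @param truth,predictions equal-length integer label vectors in
#'   `1..n_classes`.
#' @param n_classes number of classes.
#' @return an object of class `evaluation_report`: `confusion` (matrix),
#'   `overall_accuracy`, `kappa`, `macro_f1`, `per_class_f1`, `n`.
#' @export
evaluate_predictions <- function(truth, predictions, n_classes = 7L) {
  stopifnot(length(truth) == length(predictions))
  truth <- as.integer(truth); predictions <- as.integer(predictions)
  if (any(truth < 1L | truth > n_classes) ||
      any(predictions < 1L | predictions > n_classes)) {
    stop("labels must lie in 1..", n_classes)
  }
  cm <- table(factor(truth, levels = 1:n_classes),
              factor(predictions, levels = 1:n_classes))
  cm <- matrix(as.integer(cm), n_classes, n_classes,
               dimnames = list(truth = 1:n_classes,
                               prediction = 1:n_classes))
  n <- sum(cm)
  p_o <- sum(diag(cm)) / n
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else 1
  f1 <- vapply(1:n_classes, function(k) {
    tp <- cm[k, k]
    prec_den <- sum(cm[, k]); rec_den <- sum(cm[k, ])
    if (prec_den + rec_den == 0) return(NA_real_)  # class absent entirely
    prec <- if (prec_den > 0) tp / prec_den else 0
    rec <- if (rec_den > 0) tp / rec_den else 0
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, 0)
  structure(list(confusion = cm, overall_accuracy = p_o, kappa = kappa,
                 macro_f1 = mean(f1, na.rm = TRUE),
                 per_class_f1 = f1, n = n),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> n = %d | accuracy %.3f | kappa %.3f | macro F1 %.3f\n",
    x$n, x$overall_accuracy, x$kappa, x$macro_f1))
  print(x$confusion)
  invisible(x)
}
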