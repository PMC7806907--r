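#' Extract per-object images from the orthomosaic
#'
#' For each segment: the bounding-box crop of the orthomosaic with pixels
#' outside the segment set to the fill value (0), plus the binary mask —
#' the raster equivalent of an extract-by-mask clip. Segments smaller than
#' `min_area` pixels are dropped (a rule-based stand-in for manual curation
#' of fragments too small to interpret).
#'
#' @param ortho 3-band [raster_grid].
#' @param segmap a [segment_map].
#' @param min_area minimum pixel count for a segment to be retained.
#' @param ids optional subset of segment ids.
#' @return named list (by segment id) of lists with `image`
#'   (rows x cols x 3, background = 0), `mask` (logical), `bbox`, `id`.
#' @export
extract_object_images <- function(ortho, segmap, min_area = 0L, ids = NULL) {
  stopifnot(inherits(ortho, "raster_grid"), inherits(segmap, "segment_map"))
  obj <- segmap$objects
  if (is.null(ids)) ids <- obj$id
  out <- list()
  skipped <- 0L
  for (i in seq_len(nrow(obj))) {
    if (!obj$id[i] %in% ids) next
    if (obj$n[i] < min_area) { skipped <- skipped + 1L; next }
    bb <- obj$bbox[[i]]
    rows <- bb["minr"]:bb["maxr"]; cols <- bb["minc"]:bb["maxc"]
    mask <- segmap$labels[rows, cols, drop = FALSE] == obj$id[i]
    img <- ortho$values[rows, cols, , drop = FALSE]
    for (b in seq_len(dim(img)[3])) {
      band <- img[, , b]
      band[!mask] <- 0
      img[, , b] <- band
    }
    out[[as.character(obj$id[i])]] <-
      list(image = img, mask = mask, bbox = bb, id = obj$id[i])
  }
  if (skipped > 0L) {
    warning(skipped, " segment(s) below min_area dropped")
  }
  out
}

#' Resample an object image to a target ground sampling distance
#'
#' Dimensions scale by `src_gsd / dst_gsd` (rounded, at least 1 px), so the
#' pixel footprint of the output matches `dst_gsd` — used to align imagery
#' of the same crowns acquired at different flight heights.
#'
#' @param image matrix or array.
#' @param src_gsd,dst_gsd source and target GSD in m/px.
#' @return resampled image with attribute `gsd = dst_gsd`.
#' @export
normalize_gsd <- function(image, src_gsd, dst_gsd) {
  if (src_gsd <= 0 || dst_gsd <= 0) stop("GSDs must be positive")
  if (src_gsd == dst_gsd) {
    attr(image, "gsd") <- dst_gsd
    return(image)
  }
  d <- if (is.matrix(image)) dim(image) else dim(image)[1:2]
  s <- src_gsd / dst_gsd
  out <- resample_bilinear(image, max(1L, round(d[1] * s)),
                           max(1L, round(d[2] * s)))
  attr(out, "gsd") <- dst_gsd
  out
}

#' Render the classified crown map
#'
#' Builds the integer class raster (0 = unlabelled background, 1-7 =
#' classes) and the classified crown polygons from a segment map and
#' per-segment predictions.
#'
#' @param segmap a [segment_map].
#' @param predicted_labels named vector (by segment id) of class labels for
#'   the segments to map; segments without predictions stay background only
#'   if absent from the names — a named `NA` raises an error.
#' @return list: `raster` (integer matrix), `features` (polygons with
#'   `class` property), `legend` (the 7 class names).
#' @export
render_class_map <- function(segmap, predicted_labels) {
  ids <- as.integer(names(predicted_labels))
  if (anyNA(predicted_labels)) {
    stop("missing prediction for segment(s): ",
         paste(ids[is.na(predicted_labels)], collapse = ", "))
  }
  lut <- rep(0L, max(segmap$labels))
  lut[ids] <- as.integer(predicted_labels)
  ras <- matrix(lut[segmap$labels], nrow(segmap$labels))
  ras[segmap$labels == 0L] <- 0L
  feats <- polygonize_segments(segmap)
  feats <- Filter(function(f) f$id %in% ids, feats)
  feats <- lapply(feats, function(f) {
    f$class <- as.integer(predicted_labels[[as.character(f$id)]])
    f
  })
  list(raster = ras, features = feats, legend = class_labels())
}

#' Run configuration
#'
#' Assembles (or reads from YAML) the configuration that drives
#' [run_pipeline()]: the synthetic scene, segmentation parameters, GLCM
#' settings, classifier choices and seeds.
#'
#' @param path optional YAML file; entries override the defaults below.
#' @param ... named overrides applied after the file.
#' @return list of class `run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(
    seed = 42L,
    scene = list(),                 # scene_spec() overrides
    segmentation = list(scale = 240, w_shape = 0.1, w_compact = 0.5,
                        layer_weights = c(1, 1, 1, 1, 1)),
    glcm = list(kernel_size = 51L, n_levels = 32L, symmetric = TRUE),
    min_object_area = 200L,
    classifier = "both",            # "svm", "cnn", or "both"
    svm = list(gamma_grid = 10^(-1:-5), cost_grid = 10^(0:5)),
    cnn = list(epochs = 20L, lr = 0.02, batch_size = 8L),
    explain = list(enabled = TRUE, layer = "conv3", n_examples = 3L),
    output_dir = NULL
  )
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  dots <- list(...)
  if (length(dots)) cfg <- utils::modifyList(cfg, dots)
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline on a synthetic scene
#'
#' Orchestrates every stage: scene generation, slope derivation, layer
#' stacking, multiresolution segmentation, segmentation scoring against the
#' reference crowns, object extraction, GLCM feature computation, fold
#' construction, SVM and/or CNN training, pooled evaluation, classified-map
#' rendering and (optionally) Guided Grad-CAM attention maps. All
#' randomness derives from `config$seed`; rerunning with the same config
#' reproduces the report exactly. When `config$output_dir` is set, every
#' artifact is written there together with the config echo, its hash and
#' the seeds.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage progress messages.
#' @return list of class `pipeline_result` with the scene, segment map,
#'   match table, feature table, fitted models, evaluation reports, class
#'   map and attention summaries.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message("[treescope] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out <- list(config = config, config_hash = config_hash(config),
              seed = config$seed)

  say("generating synthetic scene")
  spec <- do.call(scene_spec, utils::modifyList(
    list(seed = config$seed), config$scene))
  scene <- stage("simulate", generate_scene(spec))
  out$scene <- scene

  say("deriving slope and stacking layers")
  slope <- stage("slope", compute_slope(scene$dsm))
  stack <- stage("stack", stack_layers(scene$ortho, scene$dsm, slope,
                                       config$segmentation$layer_weights))

  say("segmenting crowns (scale ", config$segmentation$scale, ")")
  params <- segmentation_params(
    scale = config$segmentation$scale,
    w_shape = config$segmentation$w_shape,
    w_compact = config$segmentation$w_compact,
    layer_weights = config$segmentation$layer_weights)
  segmap <- stage("segment", multiresolution_segment(stack, params,
                                                     seed = config$seed))
  out$segmap <- segmap

  say("scoring segmentation against reference crowns")
  out$match_table <- stage("eval-seg",
    tabulate_matches(segmap, scene$references))
  out$recovery <- stage("eval-seg",
    reference_recovery(segmap, scene$references))

  say("attaching ground-truth labels")
  ref_raster <- rasterize_references(scene$references, scene$ortho)
  truth <- stage("labels", segment_truth_labels(segmap, ref_raster,
                                                scene$crowns))

  say("extracting object images")
  objs <- stage("extract", extract_object_images(
    scene$ortho, segmap, min_area = config$min_object_area,
    ids = as.integer(names(truth))))
  truth <- truth[names(objs)]

  say("computing GLCM object features (kernel ",
      config$glcm$kernel_size, ")")
  features <- stage("features", object_feature_table(
    scene$ortho, segmap, kernel_size = config$glcm$kernel_size,
    labels = truth, ids = as.integer(names(truth)),
    n_levels = config$glcm$n_levels, symmetric = config$glcm$symmetric))
  features <- features[!is.na(features$label), ]
  out$features <- features

  say("building fold plan")
  plan <- stage("folds", make_fold_plan(
    features$id, seed = config$seed,
    labels = features$label))
  out$plan <- plan

  n_classes <- 7L
  if (config$classifier %in% c("svm", "both")) {
    say("training SVM (grid search)")
    svm_fit <- stage("train-svm", train_svm_grid(
      features, plan, gamma_grid = config$svm$gamma_grid,
      cost_grid = config$svm$cost_grid))
    out$svm <- svm_fit
    out$svm_report <- evaluate_predictions(svm_fit$predictions$truth,
                                           svm_fit$predictions$prediction,
                                           n_classes)
  }

  cnn_fit <- NULL
  if (config$classifier %in% c("cnn", "both")) {
    say("preparing patches and training CNN")
    cfg <- train_config(epochs = config$cnn$epochs, lr = config$cnn$lr,
                        batch_size = config$cnn$batch_size,
                        seed = config$seed)
    patches_train <- list(); patches_eval <- list()
    i <- 0L
    for (id in names(objs)) {
      i <- i + 1L
      patches_train[[id]] <- preprocess_patch(objs[[id]]$image, "train", cfg,
                                              seed = config$seed * 100L + i)
      patches_eval[[id]] <- preprocess_patch(objs[[id]]$image, "eval", cfg)
    }
    keep <- names(objs)[names(objs) %in% as.character(features$id)]
    cnn_fit <- stage("train-cnn", train_cnn(
      list(train = patches_train[keep], eval = patches_eval[keep]),
      stats::setNames(truth[keep], keep), plan, cfg, n_classes))
    out$cnn <- cnn_fit
    out$cnn_report <- evaluate_predictions(cnn_fit$predictions$truth,
                                           cnn_fit$predictions$prediction,
                                           n_classes)
    out$patches_eval <- patches_eval
  }

  say("rendering classified map")
  pred_source <- if (!is.null(cnn_fit)) cnn_fit$predictions else
    out$svm$predictions
  preds <- stats::setNames(pred_source$prediction,
                           as.character(pred_source$id))
  out$class_map <- stage("map", render_class_map(segmap, preds))

  if (isTRUE(config$explain$enabled) && !is.null(cnn_fit)) {
    say("computing Guided Grad-CAM attention")
    model <- cnn_fit$models[[1]]
    ex_ids <- utils::head(names(objs)[truth[names(objs)] != 7L],
                          config$explain$n_examples)
    out$attention <- lapply(ex_ids, function(id) {
      patch <- out$patches_eval[[id]]
      cls <- truth[[id]]
      cam <- grad_cam(model, patch, cls, layer = config$explain$layer)
      gbp <- guided_backprop(model, patch, cls)
      ggc <- guided_grad_cam(cam, gbp)
      mask <- preprocess_mask(objs[[id]]$mask, dim(patch)[1])
      list(id = id, class = cls, cam = cam, guided = ggc,
           inside_fraction = attention_inside_fraction(ggc, mask))
    })
  }

  if (!is.null(config$output_dir)) write_artifacts(out, config$output_dir)
  class(out) <- "pipeline_result"
  out
}

# eval-protocol resize of a mask (nearest-neighbour via bilinear threshold)
preprocess_mask <- function(mask, patch_size) {
  m <- resample_bilinear(matrix(as.numeric(mask), nrow(mask)), 256, 256)
  r0 <- floor((256 - patch_size) / 2) + 1L
  m <- m[r0:(r0 + patch_size - 1L), r0:(r0 + patch_size - 1L)]
  m >= 0.5
}

# majority ground-truth class per segment from the rasterized references
segment_truth_labels <- function(segmap, ref_raster, crowns) {
  crown_class <- c(stats::setNames(crowns$class, crowns$id))
  seg <- as.vector(segmap$labels)
  ref <- as.vector(ref_raster)
  cls <- ifelse(ref == 0L, 7L, crown_class[as.character(ref)])
  tab <- table(seg, cls)
  lab <- as.integer(colnames(tab))[apply(tab, 1, which.max)]
  stats::setNames(lab, rownames(tab))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> seed", x$seed, "| config", x$config_hash, "\n")
  cat(" segments:", nrow(x$segmap$objects), "\n")
  if (!is.null(x$svm_report)) {
    cat(sprintf(" SVM  : accuracy %.3f kappa %.3f macro F1 %.3f\n",
                x$svm_report$overall_accuracy, x$svm_report$kappa,
                x$svm_report$macro_f1))
  }
  if (!is.null(x$cnn_report)) {
    cat(sprintf(" CNN  : accuracy %.3f kappa %.3f macro F1 %.3f\n",
                x$cnn_report$overall_accuracy, x$cnn_report$kappa,
                x$cnn_report$macro_f1))
  }
  invisible(x)
}

write_artifacts <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(seed = out$seed, config_hash = out$config_hash)
  jsonlite::write_json(meta, file.path(dir, "run_meta.json"),
                       auto_unbox = TRUE)
  yaml::write_yaml(unclass(out$config), file.path(dir, "config_echo.yaml"))
  write_raster(out$scene$ortho, file.path(dir, "ortho.tif"))
  lab <- raster_grid(out$segmap$labels + 0, out$segmap$origin,
                     out$segmap$cell_size, band_names = "segment_id")
  write_raster(lab, file.path(dir, "segments.tif"), encoding = "float")
  write_geojson(polygonize_segments(out$segmap),
                file.path(dir, "segments.geojson"))
  utils::write.csv(out$match_table, file.path(dir, "match_table.csv"),
                   row.names = FALSE)
  utils::write.csv(out$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  if (!is.null(out$svm_report)) {
    utils::write.csv(out$svm_report$confusion,
                     file.path(dir, "svm_confusion.csv"))
  }
  if (!is.null(out$cnn_report)) {
    utils::write.csv(out$cnn_report$confusion,
                     file.path(dir, "cnn_confusion.csv"))
  }
  cm <- raster_grid(out$class_map$raster + 0, out$segmap$origin,
                    out$segmap$cell_size, band_names = "class")
  write_raster(cm, file.path(dir, "class_map.tif"), encoding = "float")
  write_geojson(out$class_map$features, file.path(dir, "class_map.geojson"))
  if (!is.null(out$attention)) {
    for (at in out$attention) {
      ov <- render_overlay(out$patches_eval[[at$id]], at$guided)
      save_png(ov, file.path(dir, paste0("attention_", at$id, ".png")))
    }
  }
  invisible(dir)
}
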