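# Shared fixtures for the heavier benchmark tests: the default synthetic
# scene and its derived products are computed once per test session.
.ts_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.ts_cache[[key]])) .ts_cache[[key]] <- force(expr)
  .ts_cache[[key]]
}

default_scene <- function() cached("scene", generate_scene(scene_spec()))

default_segmap <- function() {
  cached("segmap", {
    sc <- default_scene()
    slope <- compute_slope(sc$dsm)
    stack <- stack_layers(sc$ortho, sc$dsm, slope)
    multiresolution_segment(stack, segmentation_params(scale = 240),
                            seed = 42)
  })
}

default_truth <- function() {
  cached("truth", {
    sc <- default_scene()
    sm <- default_segmap()
    rr <- rasterize_references(sc$references, sc$ortho)
    treescope:::segment_truth_labels(sm, rr, sc$crowns)
  })
}

default_objects <- function() {
  cached("objects", {
    truth <- default_truth()
    suppressWarnings(extract_object_images(
      default_scene()$ortho, default_segmap(), min_area = 200,
      ids = as.integer(names(truth))))
  })
}

default_features <- function() {
  cached("features", {
    truth <- default_truth()
    ids <- as.integer(names(default_objects()))
    suppressWarnings(object_feature_table(
      default_scene()$ortho, default_segmap(), kernel_size = 51L,
      labels = truth, ids = ids))
  })
}

default_plan <- function() {
  cached("plan", {
    ft <- default_features()
    make_fold_plan(ft$id, seed = 42, labels = ft$label)
  })
}

default_cnn <- function() {
  cached("cnn", {
    objs <- default_objects()
    truth <- default_truth()[names(objs)]
    cfg <- train_config(epochs = 20L, lr = 0.02, batch_size = 8L, seed = 42)
    pt <- list(); pe <- list(); i <- 0L
    for (id in names(objs)) {
      i <- i + 1L
      pt[[id]] <- preprocess_patch(objs[[id]]$image, "train", cfg,
                                   seed = 4200L + i)
      pe[[id]] <- preprocess_patch(objs[[id]]$image, "eval", cfg)
    }
    fit <- train_cnn(list(train = pt, eval = pe), truth, default_plan(),
                     cfg, 7L)
    list(fit = fit, patches_eval = pe, truth = truth)
  })
}

# a deliberately tiny trained CNN for explainability tests
toy_cnn_config <- function() {
  train_config(patch_size = 32L, resize_size = 36L, stem_pool = 4L,
               channels = c(4L, 6L, 6L), epochs = 10L, lr = 0.05,
               batch_size = 4L, seed = 7)
}
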