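test_that("grey quantization maps 8-bit values onto 5-bit levels", {
  expect_equal(quantize_grey(matrix(0), 5L)[1, 1], 0L)
  expect_equal(quantize_grey(matrix(255), 5L)[1, 1], 31L)
  expect_equal(quantize_grey(matrix(8), 5L)[1, 1], 1L)
  expect_equal(quantize_grey(matrix(7.9), 5L)[1, 1], 0L)
  expect_error(quantize_grey(matrix(300), 5L), "\\[0, 255\\]")
  m <- matrix(sample(0:255, 100, TRUE), 10)
  lv <- quantize_grey(m, 5L)
  expect_true(all(lv >= 0 & lv <= 31))
  expect_equal(lv, floor(m / 8), ignore_attr = TRUE)
})

test_that("GLCM of simple windows matches hand counts", {
  # constant window: single diagonal entry 1
  P <- compute_glcm(matrix(3L, 4, 4), n_levels = 8)
  expect_equal(sum(P), 1)
  expect_equal(unclass(P)[4, 4], 1)
  # 1x2 window [0, 1], single offset, symmetric
  P2 <- compute_glcm(matrix(c(0L, 1L), 1, 2), n_levels = 2,
                     offsets = matrix(c(0L, 1L), 1), symmetric = TRUE)
  expect_equal(unclass(P2), matrix(c(0, 0.5, 0.5, 0), 2),
               ignore_attr = TRUE)
  expect_error(compute_glcm(matrix(0L, 1, 1), n_levels = 2), "too small")
  expect_error(compute_glcm(matrix(5L, 2, 2), n_levels = 4), "n_levels")
})

test_that("GLCM and statistics match the enumeration oracles", {
  set.seed(31)
  for (rep in 1:10) {
    w <- matrix(sample(0:3, 25, TRUE), 5)
    sym <- rep %% 2 == 0
    P <- compute_glcm(w, n_levels = 4, symmetric = sym)
    expect_equal(unclass(P), oracle_glcm(w, 4, glcm_offsets(), sym),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(sum(P), 1, tolerance = 1e-9)
    expect_true(all(P >= 0))
    if (sym) expect_equal(unclass(P), t(unclass(P)))
    st <- texture_stats(P)
    want <- oracle_texture_stats(unclass(P))
    expect_equal(unlist(st), want, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("texture statistics of degenerate and uniform GLCMs are exact", {
  P <- compute_glcm(matrix(7L, 3, 3), n_levels = 32)
  st <- texture_stats(P)
  expect_equal(st$asm, 1)
  expect_equal(st$contrast, 0)
  expect_equal(st$dissimilarity, 0)
  expect_equal(st$entropy, 0)
  expect_equal(st$homogeneity, 1)
  # uniform P over all N^2 cells
  N <- 6
  U <- matrix(1 / N^2, N, N)
  expect_equal(texture_stats(U)$asm, 1 / N^2)
  expect_error(texture_stats(U * 2), "normalized")
})

test_that("constant windows are the unique optimum of ASM and homogeneity", {
  set.seed(32)
  for (rep in 1:12) {
    w <- matrix(sample(0:7, 16, TRUE), 4)
    st <- texture_stats(compute_glcm(w, n_levels = 8))
    const <- length(unique(as.vector(w))) == 1L
    expect_equal(st$asm == 1, const)
    expect_equal(st$homogeneity == 1, const)
    expect_equal(st$contrast == 0, const)
    expect_equal(st$entropy == 0, const)
  }
})

test_that("texture maps equal the per-window pipeline on every valid pixel", {
  set.seed(33)
  img <- matrix(sample(0:255, 144, TRUE), 12)
  k <- 5L
  tm <- texture_maps(img, kernel_size = k, n_levels = 32)
  h <- (k - 1L) / 2L
  lv <- quantize_grey(img, 5L)
  for (r in seq(h + 1L, 12L - h)) {
    for (cc in seq(h + 1L, 12L - h)) {
      win <- lv[(r - h):(r + h), (cc - h):(cc + h)]
      st <- texture_stats(compute_glcm(win, n_levels = 32))
      expect_equal(tm$asm[r, cc], st$asm, tolerance = 1e-12)
      expect_equal(tm$contrast[r, cc], st$contrast, tolerance = 1e-12)
      expect_equal(tm$dissimilarity[r, cc], st$dissimilarity,
                   tolerance = 1e-12)
      expect_equal(tm$entropy[r, cc], st$entropy, tolerance = 1e-12)
      expect_equal(tm$homogeneity[r, cc], st$homogeneity, tolerance = 1e-12)
    }
  }
  # margin arithmetic
  expect_equal(sum(!is.na(tm$asm)), (12 - k + 1)^2)
  expect_error(texture_maps(img, kernel_size = 4L), "odd")
})

test_that("texture maps are translation-equivariant on the interior", {
  set.seed(34)
  img <- matrix(sample(0:255, 400, TRUE), 20)
  sh <- cbind(img[, 3:20], matrix(sample(0:255, 40, TRUE), 20))
  a <- texture_maps(img, 7L)$contrast
  b <- texture_maps(sh, 7L)$contrast
  expect_equal(b[4:17, 4:15], a[4:17, 6:17], tolerance = 1e-12)
})

test_that("constant images give flat degenerate texture maps", {
  img <- matrix(128, 10, 10)
  tm <- texture_maps(img, 3L)
  valid <- !is.na(tm$contrast)
  expect_true(all(tm$contrast[valid] == 0))
  expect_true(all(tm$homogeneity[valid] == 1))
  expect_true(all(tm$asm[valid] == 1))
})

test_that("object feature vectors have width 16 and exact moments", {
  set.seed(35)
  img <- array(sample(0:255, 10 * 10 * 3, TRUE), c(10, 10, 3))
  tm <- texture_maps(to_grey(img), 3L)
  mask <- matrix(FALSE, 10, 10); mask[4:6, 4:6] <- TRUE
  fv <- object_feature_vector(mask, img, tm)
  expect_equal(ncol(fv), 16)
  v <- img[, , 1][mask]
  expect_equal(fv$R_mean, mean(v))
  expect_equal(fv$R_sd, sqrt(mean((v - mean(v))^2)))
  # two-pixel object: hand arithmetic on the band moments
  m2 <- matrix(FALSE, 10, 10); m2[5, 5:6] <- TRUE
  fv2 <- object_feature_vector(m2, img, tm)
  x <- img[5, 5:6, 2]
  expect_equal(fv2$G_mean, (x[1] + x[2]) / 2)
  expect_equal(fv2$G_sd, abs(x[1] - x[2]) / 2)
  # constant-colour object has zero band SDs
  img_c <- array(100, c(10, 10, 3))
  fvc <- object_feature_vector(mask, img_c, texture_maps(to_grey(img_c), 3L))
  expect_equal(fvc$R_sd + fvc$G_sd + fvc$B_sd, 0)
  expect_equal(fvc$contrast_mean, 0)
  expect_equal(fvc$homogeneity_mean, 1)
  # an object fully inside the margin is an error
  edge_mask <- matrix(FALSE, 10, 10); edge_mask[1, 1] <- TRUE
  expect_error(object_feature_vector(edge_mask, img, tm), "margin")
})

test_that("kernel sweep selects the validation-accuracy argmax", {
  # two classes distinguished only by texture correlation length, on a
  # texture-only scene (identical class colours)
  set.seed(36)
  sc <- generate_scene(scene_spec(size = 224L, n_crowns = 10L,
                                  classes = c(1L, 6L), seed = 3L,
                                  class_colours = matrix(130, 6, 3),
                                  colour_sd = rep(30, 6),
                                  texture_len = c(0.6, rep(1, 4), 12)))
  slope <- compute_slope(sc$dsm)
  st <- stack_layers(sc$ortho, sc$dsm, slope)
  sm <- multiresolution_segment(st, segmentation_params(scale = 200),
                                seed = 1)
  rr <- rasterize_references(sc$references, sc$ortho)
  truth <- treescope:::segment_truth_labels(sm, rr, sc$crowns)
  truth <- truth[truth != 7L]
  plan <- make_fold_plan(as.integer(names(truth)), seed = 2,
                         labels = unname(truth))
  sweep <- kernel_sweep_select(sc$ortho, sm, truth, plan,
                               sizes = c(19L, 3L, 43L),
                               gamma_grid = 10^(-1:-3),
                               cost_grid = 10^(0:2))
  # one row per size, in ascending order regardless of input order
  expect_equal(nrow(sweep$table), 3)
  expect_equal(sweep$table$kernel_size, c(3L, 19L, 43L))
  # the returned size attains the best mean validation accuracy, and ties
  # resolve toward the smallest size
  best_acc <- max(sweep$table$val_accuracy)
  tied <- sweep$table$kernel_size[sweep$table$val_accuracy == best_acc]
  expect_equal(sweep$best_size, min(tied))
  # texture-only classes are in fact separable from the co-occurrence
  # features at the selected size
  expect_gte(best_acc, 0.8)
  # single candidate size is returned as-is
  one <- kernel_sweep_select(sc$ortho, sm, truth, plan, sizes = 11L,
                             gamma_grid = 0.1, cost_grid = 10)
  expect_equal(one$best_size, 11L)
  expect_error(kernel_sweep_select(sc$ortho, sm, truth[truth == 1],
                                   plan, sizes = 3L),
               "two classes")
})
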