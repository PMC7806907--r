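test_that("merge cost of identical adjacent single pixels is zero", {
  lab <- matrix(c(1L, 2L), 1, 2)
  obj <- segment_objects(lab, matrix(c(5, 5), 1, 2))
  p <- segmentation_params(scale = 1, w_shape = 0, layer_weights = 1)
  expect_equal(merge_cost(obj[1, ], obj[2, ], p), 0)
})

test_that("merge cost matches the direct colour-term evaluation", {
  # two adjacent single pixels, values 0 and 2: merged population SD = 1,
  # n_m = 2, so the colour term is 2
  lab <- matrix(c(1L, 2L), 1, 2)
  obj <- segment_objects(lab, matrix(c(0, 2), 1, 2))
  p <- segmentation_params(scale = 1, w_shape = 0, layer_weights = 1)
  expect_equal(merge_cost(obj[1, ], obj[2, ], p), 2)
})

test_that("merge cost rejects non-adjacent segments", {
  lab <- matrix(c(1L, 2L, 3L), 1, 3)
  obj <- segment_objects(lab, matrix(c(0, 1, 2), 1, 3))
  p <- segmentation_params(scale = 1)
  expect_error(merge_cost(obj[1, ], obj[3, ], p), "not adjacent")
})

test_that("merge cost agrees with the pixel-set oracle and the C++ path", {
  set.seed(21)
  for (rep in 1:8) {
    labels <- matrix(0L, 5, 5)
    # two random adjacent rectangles
    labels[1:3, 1:2] <- 1L
    labels[1:3, 3:5] <- 2L
    labels[4:5, ] <- 3L
    vals <- array(runif(25 * 2, 0, 100), c(5, 5, 2))
    obj <- segment_objects(labels, vals)
    w <- runif(2, 0.2, 2)
    ws <- runif(1, 0, 0.6); wc <- runif(1)
    p <- segmentation_params(scale = 1, w_shape = ws, w_compact = wc,
                             layer_weights = w)
    pairs <- list(c(1, 2), c(1, 3), c(2, 3))
    for (pr in pairs) {
      i <- which(obj$id == pr[1]); j <- which(obj$id == pr[2])
      got <- merge_cost(obj[i, ], obj[j, ], p)
      want <- oracle_merge_cost(labels, vals, pr[1], pr[2], w, ws, wc)
      expect_equal(got, want, tolerance = 1e-9)
      # the compiled merge criterion evaluates the same formula
      cpp <- treescope:::mrs_pair_cost_cpp(
        c(obj$n[i], obj$n[j]),
        rbind(obj$sum[[i]], obj$sum[[j]]),
        rbind(obj$sumsq[[i]], obj$sumsq[[j]]),
        c(obj$perimeter[i], obj$perimeter[j]),
        rbind(obj$bbox[[i]], obj$bbox[[j]]),
        obj$adjacency[[i]][[as.character(pr[2])]],
        w, ws, wc)
      expect_equal(cpp, want, tolerance = 1e-9)
    }
  }
})

test_that("constant image merges to a single segment at any scale", {
  g <- raster_grid(matrix(3.3, 16, 16), cell_size = 1)
  # with pure colour heterogeneity all merges cost exactly zero
  sm <- multiresolution_segment(g, segmentation_params(scale = 0.1,
                                                       w_shape = 0),
                                seed = 1)
  expect_equal(nrow(sm$objects), 1)
  expect_true(all(sm$labels == 1L))
  # with the default shape weight a moderate scale absorbs the (bounded)
  # shape-heterogeneity increments as well
  sm2 <- multiresolution_segment(g, segmentation_params(scale = 5), seed = 1)
  expect_equal(nrow(sm2$objects), 1)
})

test_that("a two-tone image splits exactly along the contrast edge", {
  img <- matrix(10, 8, 8); img[, 5:8] <- 200
  g <- raster_grid(img, cell_size = 1)
  # enumerate the relevant costs on this grid: merging two constant
  # same-value regions costs 0; the cheapest cross-boundary merge of two
  # single pixels (10 vs 200) costs 2 * 95 = 190, so any scale with
  # 0 < scale^2 < 190 separates the halves
  p <- segmentation_params(scale = sqrt(150), w_shape = 0, layer_weights = 1)
  sm <- multiresolution_segment(g, p, seed = 1)
  expect_equal(nrow(sm$objects), 2)
  expect_equal(length(unique(as.vector(sm$labels[, 1:4]))), 1)
  expect_equal(length(unique(as.vector(sm$labels[, 5:8]))), 1)
  expect_false(sm$labels[1, 4] == sm$labels[1, 5])
})

test_that("labels always partition the grid and stats match recomputation", {
  set.seed(22)
  img <- array(runif(20 * 20 * 2, 0, 50), c(20, 20, 2))
  g <- raster_grid(img, cell_size = 1)
  sm <- multiresolution_segment(g, segmentation_params(scale = 8), seed = 5)
  expect_true(all(sm$labels >= 1))
  expect_equal(sort(unique(as.vector(sm$labels))),
               sort(sm$objects$id))
  expect_equal(sum(sm$objects$n), 400)
  # object statistics equal batch recomputation from the label grid
  re <- segment_objects(sm$labels, g)
  for (i in seq_len(nrow(re))) {
    px <- sm$labels == re$id[i]
    for (b in 1:2) {
      v <- img[, , b][px]
      expect_equal(re$mean[[i]][b], mean(v), tolerance = 1e-6)
      expect_equal(re$sd[[i]][b], sqrt(mean((v - mean(v))^2)),
                   tolerance = 1e-6)
    }
  }
})

test_that("segment count is non-increasing in the scale parameter", {
  set.seed(23)
  img <- matrix(runif(24 * 24, 0, 100), 24)
  g <- raster_grid(img, cell_size = 1)
  counts <- vapply(c(2, 5, 10, 20, 40, 80), function(s) {
    nrow(multiresolution_segment(g, segmentation_params(scale = s),
                                 seed = 9)$objects)
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("segmentation is deterministic for a fixed seed", {
  set.seed(24)
  img <- matrix(runif(144, 0, 10), 12)
  g <- raster_grid(img, cell_size = 1)
  a <- multiresolution_segment(g, segmentation_params(scale = 3), seed = 7)
  b <- multiresolution_segment(g, segmentation_params(scale = 3), seed = 7)
  expect_identical(a$labels, b$labels)
})

test_that("polygonization returns pixel-exact areas, holes included", {
  lab <- matrix(1L, 8, 8)
  lab[2:5, 2:3] <- 2L              # rectangle
  lab[6:8, 5:8] <- 3L              # corner block
  lab[3:4, 6:7] <- 4L              # hole inside segment 1
  fe <- polygonize_segments(lab, world = FALSE)
  areas <- vapply(fe, function(f) treescope:::polygon_area(f$polygon), 0)
  ids <- vapply(fe, `[[`, 0, "id")
  for (k in seq_along(ids)) {
    expect_equal(areas[k], sum(lab == ids[k]))
  }
  expect_equal(sum(areas), 64)
  # the enclosing segment carries a hole
  f1 <- fe[[which(ids == 1)]]
  expect_false(is.matrix(f1$polygon))
  expect_equal(length(f1$polygon$holes), 2)
})

test_that("polygonization handles an L-shape and maps to world coordinates", {
  lab <- matrix(2L, 5, 5)
  lab[1:4, 1:2] <- 1L
  lab[4, 3:5] <- 1L
  lab[5, ] <- 1L
  fe <- polygonize_segments(lab, world = FALSE)
  f <- fe[[1]]
  expect_equal(treescope:::polygon_area(f$polygon), sum(lab == 1))

  sm <- structure(list(labels = lab, cell_size = 0.5, origin = c(10, 20)),
                  class = "segment_map")
  few <- polygonize_segments(sm, world = TRUE)
  expect_equal(treescope:::polygon_area(few[[1]]$polygon),
               sum(lab == 1) * 0.25)
})
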