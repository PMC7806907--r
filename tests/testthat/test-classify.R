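test_that("fold plans partition items with 4 role rotations", {
  plan <- make_fold_plan(1:8, seed = 3)
  expect_equal(length(plan$subsets), 4)
  expect_true(all(vapply(plan$subsets, length, 0L) == 2L))
  expect_setequal(unlist(plan$subsets), 1:8)
  expect_equal(length(plan$rotations), 4)
  # every item serves as test exactly once
  test_items <- unlist(lapply(plan$rotations, `[[`, "test"))
  expect_setequal(test_items, 1:8)
  expect_equal(length(test_items), 8)
  for (rot in plan$rotations) {
    expect_equal(length(intersect(rot$train, rot$test)), 0)
    expect_equal(length(intersect(rot$train, rot$validation)), 0)
    expect_equal(length(intersect(rot$validation, rot$test)), 0)
    expect_setequal(c(rot$train, rot$validation, rot$test), 1:8)
  }
  expect_identical(make_fold_plan(1:8, seed = 3), plan)
  expect_error(make_fold_plan(1:3, seed = 1), "at least 4")
})

test_that("stratified fold plans keep every class in every subset", {
  ids <- 1:24
  labels <- rep(1:4, each = 6)
  plan <- make_fold_plan(ids, seed = 5, labels = labels)
  expect_setequal(unlist(plan$subsets), ids)
  for (s in plan$subsets) {
    expect_setequal(unique(labels[s]), 1:4)
  }
})

test_that("dihedral augmentation yields the full 8-element orbit", {
  img <- matrix(c(1, 3, 2, 4), 2, 2)
  out <- augment_dihedral(img)
  expect_equal(length(out), 8)
  keys <- vapply(out, function(m) paste(m, collapse = ","), "")
  expect_equal(length(unique(keys)), 8)      # pairwise distinct
  expect_true(paste(img, collapse = ",") %in% keys)   # identity included
  # group closure: transforming any output stays within the orbit
  for (o in out) {
    keys2 <- vapply(augment_dihedral(o), function(m)
      paste(m, collapse = ","), "")
    expect_true(all(keys2 %in% keys))
  }
  # full symmetry collapses the orbit
  const <- augment_dihedral(matrix(5, 3, 3))
  expect_true(all(vapply(const, function(m) all(m == 5), TRUE)))
  # 3-band images transform band-wise
  arr <- array(runif(2 * 2 * 3), c(2, 2, 3))
  out3 <- augment_dihedral(arr)
  expect_equal(dim(out3[[2]]), c(2, 2, 3))
  expect_equal(out3[[2]][, , 2], arr[, 2:1, 2])
})

test_that("patch preprocessing follows the resize/crop protocol", {
  cfg <- train_config()
  img <- array(runif(400 * 400 * 3), c(400, 400, 3))
  out <- preprocess_patch(img, "eval", cfg)
  expect_equal(dim(out), c(224, 224, 3))
  # 256 x 256 input: the centre crop starts at offset 16
  img2 <- array(runif(256 * 256 * 3), c(256, 256, 3))
  out2 <- preprocess_patch(img2, "eval", cfg)
  expect_equal(out2, img2[17:240, 17:240, ])
  # train mode is deterministic under a fixed seed
  a <- preprocess_patch(img, "train", cfg, seed = 9)
  b <- preprocess_patch(img, "train", cfg, seed = 9)
  expect_identical(a, b)
  expect_equal(dim(a), c(224, 224, 3))
  # small images are upscaled, never an error
  tiny <- matrix(runif(64), 8)
  expect_equal(dim(preprocess_patch(tiny, "eval", cfg)), c(224, 224))
})

test_that("SVM grid search spans 30 decade pairs and fits separable data", {
  set.seed(41)
  n <- 48
  labels <- rep(1:2, each = n / 2)
  f <- matrix(rnorm(n * 16, mean = rep(labels * 6, 16)), n, 16)
  colnames(f) <- c(paste0(rep(c("R", "G", "B"), each = 2), "_",
                          c("mean", "sd")),
                   paste0(rep(c("asm", "contrast", "dissimilarity",
                                "entropy", "homogeneity"), each = 2), "_",
                          c("mean", "sd")))
  features <- tibble::as_tibble(f)
  features$id <- 1:n
  features$label <- labels
  plan <- make_fold_plan(features$id, seed = 2, labels = labels)
  fit <- train_svm_grid(features, plan)
  expect_equal(fit$grid_size, 30)   # 5 gamma x 6 cost decade steps
  expect_true(any(fit$rotations$val_accuracy == 1.0))
  expect_equal(nrow(fit$predictions), n)  # pooled test predictions
  # deterministic selection
  fit2 <- train_svm_grid(features, plan)
  expect_identical(fit$rotations, fit2$rotations)
  expect_identical(fit$predictions, fit2$predictions)
  # single-class folds are rejected
  features$label <- rep(1L, n)
  expect_error(train_svm_grid(features, plan), "two classes")
})

test_that("evaluation metrics match closed-form hand computations", {
  # worked 2-class matrix [[40, 10], [5, 45]]
  truth <- rep(c(1, 2), c(50, 50))
  pred <- c(rep(1, 40), rep(2, 10), rep(1, 5), rep(2, 45))
  rep_ <- evaluate_predictions(truth, pred, n_classes = 2)
  expect_equal(unname(rep_$confusion),
               matrix(c(40L, 5L, 10L, 45L), 2))
  expect_equal(rep_$overall_accuracy, 0.85)
  expect_equal(rep_$kappa, 0.70)
  f1a <- 2 * (40 / 45) * (40 / 50) / (40 / 45 + 40 / 50)
  f1b <- 2 * (45 / 55) * (45 / 50) / (45 / 55 + 45 / 50)
  expect_equal(rep_$per_class_f1, c(f1a, f1b))
  expect_equal(rep_$macro_f1, (f1a + f1b) / 2, tolerance = 1e-12)
  expect_equal(round(rep_$macro_f1, 4), 0.8496)

  perfect <- evaluate_predictions(1:7, 1:7, 7)
  expect_equal(perfect$overall_accuracy, 1)
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$macro_f1, 1)

  # constant prediction on a balanced 2-class set: chance agreement
  const <- evaluate_predictions(rep(c(1, 2), 10), rep(1, 20), 2)
  expect_equal(const$kappa, 0)
  expect_error(evaluate_predictions(c(1, 8), c(1, 1), 7), "1..7")
})

test_that("kappa never exceeds accuracy and is relabelling-invariant", {
  set.seed(42)
  for (rep_i in 1:10) {
    truth <- sample(1:4, 60, TRUE)
    pred <- ifelse(runif(60) < 0.6, truth, sample(1:4, 60, TRUE))
    r <- evaluate_predictions(truth, pred, 4)
    expect_lte(r$kappa, r$overall_accuracy + 1e-12)
    perm <- sample(1:4)
    r2 <- evaluate_predictions(perm[truth], perm[pred], 4)
    expect_equal(r2$kappa, r$kappa, tolerance = 1e-12)
    expect_equal(r2$overall_accuracy, r$overall_accuracy, tolerance = 1e-12)
  }
})

test_that("macro F1 is stable under per-class frequency scaling", {
  truth <- rep(c(1, 2), c(50, 50))
  pred <- c(rep(1, 40), rep(2, 10), rep(1, 5), rep(2, 45))
  r <- evaluate_predictions(truth, pred, 2)
  # triple class 1's rows: accuracy moves, macro F1 moves differently,
  # per-class recalls are unchanged
  truth3 <- c(rep(truth[1:50], 3), truth[51:100])
  pred3 <- c(rep(pred[1:50], 3), pred[51:100])
  r3 <- evaluate_predictions(truth3, pred3, 2)
  expect_false(isTRUE(all.equal(r3$overall_accuracy, r$overall_accuracy)))
  rec1 <- r$confusion[1, 1] / sum(r$confusion[1, ])
  rec1_3 <- r3$confusion[1, 1] / sum(r3$confusion[1, ])
  expect_equal(rec1_3, rec1)
})
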