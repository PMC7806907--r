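unit_sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
shifted <- function(poly, dx, dy) cbind(poly[, 1] + dx, poly[, 2] + dy)
ref <- function(poly, class = 1, id = 1) list(polygon = poly, class = class,
                                              id = id)

test_that("overlap fraction handles identity, disjoint and partial cover", {
  expect_equal(overlap_fraction(unit_sq, ref(unit_sq)), 1.0)
  expect_equal(overlap_fraction(shifted(unit_sq, 5, 5), ref(unit_sq)), 0.0)
  left_half <- cbind(c(0, 0.5, 0.5, 0), c(0, 0, 1, 1))
  expect_equal(overlap_fraction(left_half, ref(unit_sq)), 0.5)
  expect_error(overlap_fraction(unit_sq, ref(unit_sq[c(1, 1, 1), ])),
               "zero area")
})

test_that("intersection-over-union mode divides by the union", {
  left_half <- cbind(c(0, 0.5, 0.5, 0), c(0, 0, 1, 1))
  expect_equal(overlap_fraction(left_half, ref(unit_sq), mode = "iou"), 0.5)
  big <- cbind(c(0, 2, 2, 0), c(0, 0, 1, 1))
  expect_equal(overlap_fraction(big, ref(unit_sq), mode = "iou"), 0.5)
  expect_equal(overlap_fraction(big, ref(unit_sq)), 1.0)
})

test_that("single-reference overlaps map to Matched/NearlyMatched/Split", {
  make_seg <- function(frac) cbind(c(0, frac, frac, 0), c(0, 0, 1, 1))
  refs <- list(ref(unit_sq))
  expect_equal(as.character(categorize_segment(make_seg(0.85), refs)),
               "Matched")
  expect_equal(as.character(categorize_segment(make_seg(0.80), refs)),
               "NearlyMatched")   # exactly 80% is not "more than 80%"
  expect_equal(as.character(categorize_segment(make_seg(0.40), refs)),
               "Split")
  expect_equal(as.character(categorize_segment(make_seg(0.60), refs)),
               "Split")           # boundary closes downward
  expect_equal(as.character(categorize_segment(make_seg(0.10), refs)),
               "Fragmented")
  expect_equal(as.character(categorize_segment(make_seg(0.20), refs)),
               "Fragmented")      # exactly 20% does not exceed the floor
})

test_that("multiple covered references yield Merged categories", {
  # segment spanning two unit squares side by side
  seg <- cbind(c(0, 2, 2, 0), c(0, 0, 1, 1))
  r1 <- ref(unit_sq, class = 2, id = 1)
  r2 <- ref(shifted(unit_sq, 1, 0), class = 2, id = 2)
  r3 <- ref(shifted(unit_sq, 1, 0), class = 5, id = 3)
  expect_equal(as.character(categorize_segment(seg, list(r1, r2))),
               "MergedOneClass")
  expect_equal(as.character(categorize_segment(seg, list(r1, r3))),
               "MergedMultiClass")
  # overlaps 0.30 and 0.25 of two same-class crowns
  seg2b <- cbind(c(0.7, 1.25, 1.25, 0.7), c(0, 0, 1, 1))
  two <- list(ref(unit_sq, class = 3, id = 1),
              ref(shifted(unit_sq, 1, 0), class = 3, id = 2))
  got <- categorize_segment(seg2b, two)
  expect_equal(as.character(got), "MergedOneClass")
  expect_equal(unname(round(attr(got, "overlaps"), 10)), c(0.30, 0.25))
  # three references all at 10% overlap
  wide <- cbind(c(0, 3, 3, 0), c(0, 0, 0.1, 0.1))
  three <- list(ref(unit_sq, 1, 1), ref(shifted(unit_sq, 1, 0), 2, 2),
                ref(shifted(unit_sq, 2, 0), 3, 3))
  expect_equal(as.character(categorize_segment(wide, three)), "Fragmented")
  expect_error(categorize_segment(unit_sq, list()), "at least one")
})

test_that("category responds monotonically as one overlap grows", {
  refs <- list(ref(unit_sq))
  order_rank <- c(Fragmented = 1, Split = 2, NearlyMatched = 3, Matched = 4)
  fr <- seq(0.05, 0.95, by = 0.05)
  cats <- vapply(fr, function(f) {
    as.character(categorize_segment(cbind(c(0, f, f, 0), c(0, 0, 1, 1)),
                                    refs))
  }, "")
  expect_true(all(diff(order_rank[cats]) >= 0))
})

test_that("categorization is invariant to reference ordering", {
  seg <- cbind(c(0, 1.4, 1.4, 0), c(0, 0, 1, 1))
  refs <- list(ref(unit_sq, 1, 1), ref(shifted(unit_sq, 1, 0), 4, 2),
               ref(shifted(unit_sq, 3, 0), 2, 3))
  a <- as.character(categorize_segment(seg, refs))
  b <- as.character(categorize_segment(seg, rev(refs)))
  expect_equal(a, b)
})

test_that("a perfectly recovered rasterized scene tabulates as all Matched", {
  sq <- function(x0, y0, w) cbind(c(x0, x0 + w, x0 + w, x0),
                                  c(y0, y0, y0 + w, y0 + w))
  refs <- list(ref(sq(0.5, 0.5, 1.4), 1, 1), ref(sq(2.5, 0.5, 1.2), 2, 2),
               ref(sq(0.5, 2.5, 1.0), 3, 3))
  grid <- raster_grid(array(0, c(50, 50, 1)), origin = c(0, 5),
                      cell_size = 0.1)
  lab <- rasterize_references(refs, grid)
  lab[lab == 0L] <- 4L   # background as its own segment
  sm <- structure(list(labels = lab, cell_size = 0.1, origin = c(0, 5)),
                  class = "segment_map")
  tab <- tabulate_matches(sm, refs)
  expect_equal(tab$matched, 3)
  expect_equal(tab$nearly_matched + tab$split + tab$merged_one_class +
                 tab$merged_multi_class + tab$fragmented, 0)
  expect_equal(tab$n_segments, 3)   # background excluded as non-forest
  # counts always sum to the evaluated segments
  expect_equal(tab$matched + tab$nearly_matched + tab$split +
                 tab$merged_one_class + tab$merged_multi_class +
                 tab$fragmented, tab$n_segments)
})

test_that("a reference split into two equal segments counts both as Split", {
  refs <- list(ref(cbind(c(0, 2, 2, 0), c(0, 0, 2, 2)), 1, 1))
  lab <- matrix(0L, 20, 20)
  lab[, 1:10] <- 1L; lab[, 11:20] <- 2L
  sm <- structure(list(labels = lab, cell_size = 0.1, origin = c(0, 2)),
                  class = "segment_map")
  tab <- tabulate_matches(sm, refs)
  expect_equal(tab$split, 2)
  expect_equal(tab$n_segments, 2)
})

test_that("reference recovery reports the best-covering segment", {
  refs <- list(ref(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)), 2, 1))
  lab <- matrix(2L, 10, 10)
  lab[1:10, 1:9] <- 1L   # covers 90% of the reference square
  sm <- structure(list(labels = lab, cell_size = 0.1, origin = c(0, 1)),
                  class = "segment_map")
  rec <- reference_recovery(sm, refs)
  expect_equal(rec$best_segment, 1)
  expect_equal(rec$best_overlap, 0.9, tolerance = 1e-9)
  expect_true(rec$recovered)
})
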