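test_that("the transition criterion fires on a clean earlywood-to-latewood step", {
  # ten sparse rows then twenty dense rows: boundary at the tenth row
  p <- profile_from_counts(c(rep(2, 10), rep(90, 20)), w = 128)
  expect_equal(find_transition_row(p), 10L)
  expect_equal(transition_row_oracle(p), 10L)

  # dark band first (latewood above earlywood reading downward): no hit
  p_rev <- profile_from_counts(c(rep(90, 10), rep(2, 20)), w = 128)
  expect_identical(find_transition_row(p_rev), NA_integer_)

  # a 30-row linear ramp: binarized one-run too short
  p_ramp <- profile_from_counts(0:29, w = 128)
  expect_identical(find_transition_row(p_ramp), NA_integer_)
})

test_that("degenerate and too-short profiles never yield a transition", {
  expect_identical(find_transition_row(profile_from_counts(rep(7, 50))),
                   NA_integer_)
  expect_identical(find_transition_row(profile_from_counts(c(rep(2, 9),
                                                             rep(90, 20)))),
                   NA_integer_)
})

test_that("criterion parameters are honoured", {
  p <- profile_from_counts(c(rep(2, 10), rep(90, 20)), w = 128)
  # shorter runs move the earliest qualifying row up
  expect_equal(find_transition_row(p, criterion_params(zero_run = 5,
                                                       one_run = 10)), 10L)
  # literal density reading: 20-row sum over w alone is far above 0.3
  expect_equal(find_transition_row(p, criterion_params(density_norm = "literal")),
               10L)
  # impossible contrast demand suppresses detection
  expect_identical(
    find_transition_row(p, criterion_params(contrast_min = 0.99)),
    NA_integer_)
  # band density: latewood at 25% black fails the 0.3 floor
  p_weak <- profile_from_counts(c(rep(0, 10), rep(32, 20)), w = 128)
  expect_identical(find_transition_row(p_weak), NA_integer_)
  expect_identical(transition_row_oracle(p_weak), NA_integer_)
})

test_that("fast scan agrees with the brute-force oracle on random profiles", {
  set.seed(31)
  hits <- 0L
  for (i in 1:200) {
    p <- random_profile()
    fast <- find_transition_row(p)
    slow <- transition_row_oracle(p)
    expect_identical(fast, slow)
    if (!is.na(fast)) hits <- hits + 1L
  }
  expect_gt(hits, 5)   # both branches really exercised
})

test_that("a strip with an abrupt transition is detected, an all-white strip is not", {
  spec <- synthetic_spec(width = 64, height = 480, abruptness = 1,
                         boundary_slope = 0, noise = 0, seed = 301)
  strip <- generate_ring_image(spec)$image
  v <- classify_subimage(strip, strip_index = 1L)
  expect_true(v$distinct)
  expect_equal(v$slope_used, 0)
  expect_false(is.na(v$transition_row))

  blank <- array(255, dim = c(200, 32, 3))
  vb <- classify_subimage(blank)
  expect_false(vb$distinct)
  expect_true(is.na(vb$transition_row))
})

test_that("a sheared abrupt strip is still detected with a sweep-candidate slope", {
  spec <- synthetic_spec(width = 128, height = 960, abruptness = 1,
                         boundary_slope = 2 / 128, noise = 0.02, seed = 302)
  strip <- generate_ring_image(spec)$image
  v <- classify_subimage(strip)
  expect_true(v$distinct)
  expect_true(v$slope_used %in% slope_candidates(128))
})

test_that("strips too small for the runs are counted as not distinct, with a warning", {
  tiny <- array(runif(20 * 32 * 3, 0, 255), dim = c(20, 32, 3))
  expect_warning(v <- classify_subimage(tiny, strip_index = 3L), "too small")
  expect_false(v$distinct)
})

test_that("the majority vote flips strictly above 50%", {
  # composite slides: k abrupt strips (width 32) padded with constant strips,
  # which binarize to all white (tau = mu) and can never be distinct
  make_slide <- function(k, n = 20L, w = 32L, h = 480L) {
    img <- array(200, dim = c(h, n * w, 3))
    for (i in seq_len(k)) {
      sp <- synthetic_spec(width = w, height = h, abruptness = 1, seed = 400 + i)
      img[, ((i - 1) * w + 1):(i * w), ] <- generate_ring_image(sp)$image
    }
    img
  }
  v11 <- classify_slide(make_slide(11L), count = 20L)
  expect_equal(v11$distinct_degree, 55)
  expect_equal(v11$label, "distinct")
  expect_equal(v11$iawa_code, "40p")

  v10 <- classify_slide(make_slide(10L), count = 20L)
  expect_equal(v10$distinct_degree, 50)
  expect_equal(v10$label, "indistinct or absent")
  expect_equal(v10$iawa_code, "41p")
})

test_that("IAWA feature codes map 1:1 onto the verdict labels", {
  expect_equal(iawa_feature_code("distinct"), "40p")
  expect_equal(iawa_feature_code("indistinct or absent"), "41p")
  expect_equal(iawa_feature_code("Distinct"), "40p")
  expect_error(iawa_feature_code("fuzzy"), "unknown")
})

test_that("distinct degree is invariant under horizontal mirroring", {
  spec <- synthetic_spec(width = 640, height = 480, abruptness = 1,
                         boundary_slope = 3 / 128, noise = 0, seed = 303)
  img <- generate_ring_image(spec)$image
  mirrored <- img[, dim(img)[2]:1, , drop = FALSE]
  v <- classify_slide(img, count = 10L)
  vm <- classify_slide(mirrored, count = 10L)
  expect_equal(v$distinct_degree, vm$distinct_degree)
})

test_that("distinct degree is monotone in transition abruptness (noise-free)", {
  degree_at <- function(a) {
    spec <- synthetic_spec(width = 2560, height = 960, abruptness = a,
                           boundary_slope = 0, noise = 0, seed = 304)
    classify_slide(generate_ring_image(spec)$image)$distinct_degree
  }
  d <- vapply(c(0, 0.6, 1), degree_at, numeric(1))
  expect_true(all(diff(d) >= 0))
  expect_equal(d[3], 100)
})

test_that("verdict objects tidy, glance and plot", {
  spec <- synthetic_spec(width = 320, height = 480, abruptness = 1, seed = 305)
  v <- classify_slide(generate_ring_image(spec)$image, count = 5L)
  td <- tidy(v)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 5)
  gl <- glance(v)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_strips, 5)
  expect_equal(gl$iawa_code, iawa_feature_code(gl$label))
  expect_s3_class(autoplot(v), "ggplot")

  b <- binarize_image(rgb_to_gray(generate_ring_image(spec)$image))
  expect_s3_class(autoplot(row_profile(b[, 1:64], 0)), "ggplot")
})
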