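test_that("intensity normalization is min-max with order preserved", {
  expect_equal(normalize_intensity(matrix(c(0, 65535, 0, 65535), 2)),
               matrix(c(0, 1, 0, 1), 2))
  expect_equal(normalize_intensity(matrix(1234, 5, 5)), matrix(0, 5, 5))
  expect_error(normalize_intensity(matrix(numeric(0), 0, 0)), "nonempty")

  withr::local_seed(11)
  raw <- matrix(sample.int(65536, 200) - 1L, 10, 20)
  u <- normalize_intensity(raw)
  expect_identical(min(u), 0)
  expect_identical(max(u), 1)
  expect_identical(order(as.vector(u)), order(as.vector(raw)))
})

test_that("hemisphere crop-and-resize recovers exact content and preserves mean", {
  # left ROI box covering exactly 80 x 96 (plus a separate right box):
  # identity content survives the no-op resize
  slice <- matrix(0, 120, 260)
  roi <- matrix(0L, 120, 260)
  content <- matrix(runif(80 * 96), 80, 96)
  slice[11:90, 5:100] <- content
  roi[11:90, 5:100] <- 1L
  roi[30:60, 180:240] <- 1L # right-hemisphere box
  got <- crop_and_resize(slice, roi, "left", out_shape = c(80, 96))
  expect_equal(got, content, tolerance = 1e-12)

  # 160 x 192 box downsampled 2x -> mean preserved within 1%
  slice2 <- matrix(0, 200, 370)
  roi2 <- matrix(0L, 200, 370)
  big <- matrix(runif(160 * 192), 160, 192)
  slice2[21:180, 171:362] <- big
  roi2[21:180, 171:362] <- 1L
  roi2[80:120, 5:60] <- 1L # left-hemisphere box, fully left of the midline
  small <- crop_and_resize(slice2, roi2, "right", out_shape = c(80, 96))
  expect_identical(dim(small), c(80L, 96L))
  expect_lt(abs(mean(small) - mean(big)) / mean(big), 0.01)

  expect_error(crop_and_resize(slice, matrix(0L, 120, 260), "left",
                               context = "S001 slice 2"),
               "empty ROI mask")
})

test_that("left and right hemispheres split the ROI bounding region", {
  sl <- local_seed_slice <- withr::with_seed(21, {
    render_slice(counts = c(3L, 5L), tiny_phantom(), slice_shape = c(160, 220))
  })
  left <- crop_and_resize(sl$raw, sl$roi_mask, "left", c(40, 48))
  right <- crop_and_resize(sl$raw, sl$roi_mask, "right", c(40, 48))
  expect_identical(dim(left), c(40L, 48L))
  expect_false(identical(left, right))
})

test_that("enhancement target pushes masked pixels to the top of the range", {
  img <- matrix(0.5, 6, 8)
  m <- matrix(0L, 6, 8)
  # empty mask: identity
  expect_identical(make_enhancement_target(img, m), img)
  # one masked pixel on a constant 0.5 image: exactly 1 there, 0 elsewhere
  m[3, 4] <- 1L
  t <- make_enhancement_target(img, m)
  expect_identical(t[3, 4], 1)
  expect_identical(max(abs(t[m == 0])), 0)

  expect_error(make_enhancement_target(img, matrix(0L, 3, 3)), "same shape")
  expect_error(make_enhancement_target(img * 3, m), "\\[0, 1\\]")
})

test_that("target ranks every masked pixel above every unmasked pixel", {
  withr::local_seed(13)
  parts <- tiny_parts(2)
  for (i in which(parts$count > 0)) {
    target <- parts$target[[i]]
    mask <- parts$mask[[i]]
    expect_gt(min(target[mask == 1]), max(target[mask == 0]))
  }
})

test_that("count normalization round-trips exactly over 0..48", {
  expect_identical(normalize_count(48), 1)
  expect_identical(normalize_count(0), 0)
  for (c in 0:48) {
    expect_identical(denormalize_count(normalize_count(c)), as.numeric(c))
  }
  expect_error(normalize_count(49), "exceeds")
  expect_identical(normalize_count(60, clip = TRUE), 1)
  expect_identical(denormalize_count(-0.02), 0)
  expect_identical(denormalize_count(1.7), 48)
})

test_that("preprocessing standardizes shape, range and labels", {
  parts <- tiny_parts(2, out_shape = c(80, 96))
  expect_s3_class(parts, "pvs_parts")
  expect_identical(nrow(parts), 12L)
  for (i in seq_len(nrow(parts))) {
    expect_unit_image(parts$image[[i]], c(80, 96))
    expect_unit_image(parts$target[[i]], c(80, 96))
    expect_true(all(parts$mask[[i]] %in% c(0L, 1L)))
  }
  expect_equal(parts$count_norm, parts$count / 48)
})
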