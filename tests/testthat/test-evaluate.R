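test_that("CNR reproduces hand arithmetic on constructed grids", {
  img <- matrix(0, 10, 12)
  sig <- sur <- bg <- matrix(0L, 10, 12)
  sig[2, 2:4] <- 1L; img[2, 2:4] <- 0.8
  sur[5, 2:7] <- 1L; img[5, 2:7] <- 0.3
  # background {0.29, 0.30, 0.31}: sample sd exactly 0.01
  bg[9, 2:4] <- 1L; img[9, 2:4] <- c(0.29, 0.30, 0.31)
  r <- compute_cnr(img, sig, sur, bg)
  expect_equal(r$mu_signal1, 0.8)
  expect_equal(r$mu_signal2, 0.3)
  expect_equal(r$sigma_noise, 0.01)
  expect_equal(r$cnr, 50.0, tolerance = 1e-9)

  # symmetry under swapping signal and surround
  expect_equal(compute_cnr(img, sur, sig, bg)$cnr, r$cnr)

  # identical constants give zero CNR
  img2 <- img; img2[2, 2:4] <- 0.3
  expect_equal(compute_cnr(img2, sig, sur, bg)$cnr, 0)

  # degenerate cases fail loudly
  img3 <- img; img3[9, 2:4] <- 0.3
  expect_error(compute_cnr(img3, sig, sur, bg), "sigma_noise is zero")
  expect_error(compute_cnr(img, sig, sig, bg), "disjoint")
  expect_error(compute_cnr(img, matrix(0L, 10, 12), sur, bg), "nonempty")
})

test_that("CNR is invariant to a shared affine intensity rescaling", {
  withr::local_seed(61)
  img <- matrix(runif(30 * 30), 30, 30)
  mask <- matrix(0L, 30, 30); mask[14:16, 14:16] <- 1L
  m <- cnr_masks(mask)
  a <- compute_cnr(img, m$signal, m$surround, m$background)$cnr
  b <- compute_cnr(0.4 * img + 0.2, m$signal, m$surround, m$background)$cnr
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("derived CNR regions are disjoint and anatomically sensible", {
  mask <- matrix(0L, 40, 48); mask[20:21, 24] <- 1L
  m <- cnr_masks(mask, ring_radius = 3, frame_width = 8)
  expect_identical(sum(m$signal * m$surround), 0L)
  expect_identical(sum(m$signal * m$background), 0L)
  expect_identical(sum(m$surround * m$background), 0L)
  expect_gt(sum(m$surround), 0)
  expect_gt(sum(m$background), 0)
  # empty-mask parts return NA instead of failing
  expect_true(is.na(part_cnr(matrix(0.5, 40, 48), matrix(0L, 40, 48))$cnr))
})

test_that("fold assignment partitions subjects with balanced sizes", {
  ids76 <- sprintf("S%03d", 1:76)
  plan <- make_folds(ids76, k = 4, seed = 1)
  expect_identical(as.integer(table(plan$fold)), c(19L, 19L, 19L, 19L))

  plan7 <- make_folds(sprintf("S%d", 1:7), k = 4, seed = 2)
  expect_identical(sort(as.integer(table(plan7$fold)), decreasing = TRUE),
                   c(2L, 2L, 2L, 1L))

  # every subject in exactly one fold
  expect_setequal(plan$subject_id, ids76)
  expect_identical(anyDuplicated(plan$subject_id), 0L)

  expect_identical(make_folds(ids76, 4, seed = 5), make_folds(ids76, 4, seed = 5))
  expect_error(make_folds(ids76, k = 1), ">= 2")
  expect_error(make_folds(sprintf("S%d", 1:3), k = 4), "at least")
})

test_that("cross-validation bookkeeping: folds, pooling, no leakage", {
  parts <- tiny_parts(8, seed = 63)
  cfg <- tiny_config()
  rep <- run_cross_validation(parts, "none", cfg, k = 4, seed = 3)
  expect_s3_class(rep, "pvs_eval")
  expect_identical(nrow(rep$predictions), 48L)
  expect_identical(sort(unique(rep$predictions$fold)), 1:4)
  expect_identical(nrow(rep$per_fold), 4L)

  # leakage audit: no subject is both trained on and tested in any fold
  for (f in seq_len(4)) {
    fs <- rep$fold_subjects[[f]]
    expect_identical(intersect(fs$train, fs$test), character(0))
    tested <- unique(rep$predictions$subject_id[rep$predictions$fold == f])
    expect_setequal(tested, fs$test)
  }
  # every subject tested exactly once
  expect_setequal(unique(rep$predictions$subject_id), unique(parts$subject_id))

  # subject accuracy equals brute-force max-aggregation
  pr <- rep$predictions
  subj_truth <- tapply(pr$truth_grade, pr$subject_id, max)
  subj_pred <- tapply(pr$pred_grade, pr$subject_id, max)
  expect_equal(rep$metrics$subject_accuracy,
               100 * mean(subj_truth == subj_pred))

  # glance returns the pooled one-row summary
  g <- generics::glance(rep)
  expect_identical(nrow(g), 1L)
  expect_true(g$image_accuracy >= 0 && g$image_accuracy <= 100)
  expect_true(abs(g$icc_image) <= 1)
})

test_that("cross-validation reruns are identical under a fixed seed", {
  parts <- tiny_parts(4, seed = 64)
  cfg <- tiny_config()
  a <- run_cross_validation(parts, "none", cfg, k = 4, seed = 7)
  b <- run_cross_validation(parts, "none", cfg, k = 4, seed = 7)
  expect_identical(a$predictions, b$predictions)
  expect_identical(a$metrics, b$metrics)
})

test_that("missing labels are rejected", {
  parts <- tiny_parts(4, seed = 65)
  parts$count[3] <- NA
  expect_error(run_cross_validation(parts, "none", tiny_config(), seed = 1),
               "missing labels")
})
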