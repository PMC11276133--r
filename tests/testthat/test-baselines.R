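test_that("white top-hat isolates small bright structures", {
  # constant image: zero residual, renormalized (constant -> all zeros)
  expect_equal(tophat_enhance(matrix(0.4, 20, 20)), matrix(0, 20, 20))

  # single bright pixel on zero background: opening removes it, the residual
  # equals the pixel, and after adding back + renormalizing the image is
  # unchanged
  img <- matrix(0, 15, 15)
  img[8, 8] <- 1
  expect_equal(tophat_enhance(img, radius = 2), img, tolerance = 1e-12)

  expect_error(tophat_enhance(img, radius = 0), ">= 1")
  expect_error(tophat_enhance(matrix(0.5, 5, 5), radius = 10), "larger")
})

test_that("CLAHE is close to identity on a uniform-histogram image", {
  withr::local_seed(31)
  # every tile holds a permutation of evenly spaced values, so each tile's
  # histogram is exactly uniform and equalization is a fixed point
  u <- matrix(0, 80, 96)
  for (a in 0:3) for (b in 0:3) {
    vals <- (seq_len(20 * 24) - 0.5) / (20 * 24)
    u[a * 20 + 1:20, b * 24 + 1:24] <- sample(vals)
  }
  out <- clahe_enhance(u, clip_limit = 0.05, tile_grid = c(4, 4))
  expect_unit_image(out)
  expect_lt(max(abs(out - u)), 0.05)
})

test_that("CLAHE preserves order and level structure of a two-level image", {
  two <- matrix(0.2, 80, 96)
  two[, seq(1, 96, by = 2)] <- 0.8 # every tile sees the same two-level histogram
  out <- clahe_enhance(two)
  expect_unit_image(out)
  expect_identical(length(unique(round(as.vector(out), 8))), 2L)
  expect_true(all(out[two == 0.8] > out[two == 0.2]))
  expect_error(clahe_enhance(two, clip_limit = 0), "positive")
  expect_error(clahe_enhance(matrix(0.5, 4, 4), tile_grid = c(8, 8)), "fit")
})

test_that("Laplacian sharpening boosts peaks and fixes harmonic regions", {
  expect_equal(laplacian_enhance(matrix(0.7, 10, 10)), matrix(0, 10, 10))

  # linear ramp: Laplacian vanishes in the interior, so the interior is
  # unchanged up to the global affine renormalization
  ramp <- matrix(rep(seq(0, 1, length.out = 30), each = 20), 20, 30)
  out <- laplacian_enhance(ramp)
  interior <- function(m) m[2:19, 2:29]
  rescale <- function(m) (m - min(m)) / (max(m) - min(m))
  expect_equal(rescale(interior(out)), rescale(interior(ramp)),
               tolerance = 1e-10)

  # single bright pixel: the 4-neighbour kernel arithmetic by hand
  img <- matrix(0, 7, 7)
  img[4, 4] <- 0.5
  lap_center <- 0 + 0 + 0 + 0 - 4 * 0.5 # = -2
  sharpened_center <- 0.5 - 1 * lap_center # = 2.5, the maximum
  out2 <- laplacian_enhance(img, weight = 1)
  expect_identical(out2[4, 4], 1) # center maps to the top of the range
  expect_equal(sharpened_center, 2.5)
  expect_error(laplacian_enhance(img, weight = 0), "positive")
})

test_that("baselines raise ePVS salience on phantom parts", {
  # statistical property over >= 50 parts. Top-hat and Laplacian raise the
  # ring-CNR of the puncta; CLAHE (which equalizes background texture along
  # with the puncta) raises the masked-vs-unmasked mean contrast instead —
  # its ring-CNR sits at/below the non-enhanced level, consistent with its
  # near-parity CNR and worst-enhancer role in the comparison it comes from.
  parts <- tiny_parts(9, seed = 33) # 54 parts
  keep <- which(parts$count > 0)
  cnr_gain <- function(fn) {
    vapply(keep, function(i) {
      part_cnr(fn(parts$image[[i]]), parts$mask[[i]])$cnr -
        part_cnr(parts$image[[i]], parts$mask[[i]])$cnr
    }, numeric(1))
  }
  expect_gt(mean(cnr_gain(tophat_enhance) > 0), 0.9)
  expect_gt(mean(cnr_gain(laplacian_enhance) > 0), 0.9)

  contrast <- function(img, mask) mean(img[mask == 1]) - mean(img[mask == 0])
  clahe_gain <- vapply(keep, function(i) {
    contrast(clahe_enhance(parts$image[[i]]), parts$mask[[i]]) -
      contrast(parts$image[[i]], parts$mask[[i]])
  }, numeric(1))
  expect_gt(mean(clahe_gain > 0), 0.75)
})

test_that("baselines are deterministic, shape- and range-preserving", {
  parts <- tiny_parts(1, seed = 35)
  img <- parts$image[[which.max(parts$count)]]
  for (fn in list(tophat_enhance, clahe_enhance, laplacian_enhance)) {
    a <- fn(img); b <- fn(img)
    expect_identical(a, b)
    expect_unit_image(a, dim(img))
    expect_identical(min(a), 0)
    expect_identical(max(a), 1)
  }
})

test_that("enhance_parts wires methods onto the parts table", {
  parts <- tiny_parts(1, seed = 36)
  none <- enhance_parts(parts, "none")
  expect_identical(none$enhanced, parts$image)
  th <- enhance_parts(parts, "tophat")
  expect_identical(length(th$enhanced), nrow(parts))
  expect_error(enhance_parts(parts, "dl"), "model")
})
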