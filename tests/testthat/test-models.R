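test_that("augmentation applies one joint geometric transform", {
  withr::local_seed(41)
  cfg <- tiny_config()
  img <- matrix(runif(40 * 48), 40, 48)

  # zero transform: identity within interpolation tolerance
  id_draw <- list(flip_x = FALSE, flip_y = FALSE, scale = 1, angle = 0)
  out <- augment_pair(img, img, cfg, draw = id_draw)
  expect_lt(max(abs(out$input - img)), 1e-6)

  # flips are involutions
  fl <- list(flip_x = TRUE, flip_y = TRUE, scale = 1, angle = 0)
  once <- augment_pair(img, img, cfg, draw = fl)$input
  twice <- augment_pair(once, once, cfg, draw = fl)$input
  expect_lt(max(abs(twice - img)), 1e-6)

  # count labels pass through unchanged
  expect_identical(augment_pair(img, 0.25, cfg)$target, 0.25)
})

test_that("joint transforms keep masked pixels the brightest in the target", {
  withr::local_seed(42)
  parts <- tiny_parts(2, seed = 42)
  cfg <- tiny_config()
  i <- which(parts$count >= 5)[1]
  for (rep in 1:5) {
    ap <- augment_pair(parts$image[[i]], parts$target[[i]], cfg)
    am <- augment_pair(parts$mask[[i]] * 1.0, parts$mask[[i]] * 1.0, cfg,
                       draw = ap$draw, interpolation = "nearest")
    m <- am$input >= 0.5
    if (sum(m) == 0) next
    inside <- mean(ap$target[m])
    outside <- mean(ap$target[!m])
    expect_gt(inside, outside)
  }
})

test_that("the enhancer learns the identity map on a tiny problem", {
  withr::local_seed(43)
  # smooth tissue-like images; full-batch training keeps the batch-norm
  # statistics stable enough for the identity to be reached exactly
  imgs <- lapply(1:16, function(i) {
    normalize_intensity(render_part(0, phantom_params(part_shape = c(16L, 16L)))$raw)
  })
  cfg <- train_config("desk", enhancer_depth = 2L, enhancer_base_filters = 8L,
                      epochs_enhancer = 150L, batch_size = 16L, augment = FALSE,
                      learning_rate = 1e-2)
  fit <- train_enhancer(list(input = imgs, target = imgs), cfg, seed = 1)
  expect_lt(fit$history$loss[150], 1e-3)
  expect_lte(fit$history$loss[150], fit$history$loss[1])
  out <- enhance(fit, imgs[[1]])
  expect_unit_image(out, c(16, 16))
})

test_that("the enhancer can overfit a single pair", {
  withr::local_seed(44)
  img <- matrix(runif(16 * 16), 16, 16)
  tgt <- matrix(runif(16 * 16), 16, 16)
  cfg <- train_config("desk", enhancer_depth = 2L, enhancer_base_filters = 8L,
                      epochs_enhancer = 150L, batch_size = 2L, augment = FALSE,
                      learning_rate = 3e-3)
  fit <- train_enhancer(list(input = list(img, img), target = list(tgt, tgt)),
                        cfg, seed = 2)
  expect_lt(min(fit$history$loss), 1e-4)
})

test_that("training is deterministic under a fixed seed", {
  parts <- tiny_parts(2, seed = 45)
  cfg <- tiny_config()
  a <- train_enhancer(parts, cfg, seed = 9)
  b <- train_enhancer(parts, cfg, seed = 9)
  expect_identical(a$history, b$history)
  expect_identical(a$P, b$P)
  qa <- train_quantifier(parts$image, parts$count_norm, cfg, seed = 9)
  qb <- train_quantifier(parts$image, parts$count_norm, cfg, seed = 9)
  expect_identical(qa$history, qb$history)
})

test_that("enhancer inference respects shape, order and output contracts", {
  parts <- tiny_parts(1, seed = 46)
  cfg <- tiny_config(epochs_enhancer = 1L)
  fit <- train_enhancer(parts, cfg, seed = 3)

  # zeroed output head: sigmoid(0) everywhere -> constant 0.5
  zeroed <- fit
  zeroed$P$out_w[] <- 0
  zeroed$P$out_b <- 0
  const <- enhance(zeroed, parts$image[[1]])
  expect_lt(max(abs(const - 0.5)), 1e-12)

  outs <- enhance(fit, parts$image)
  expect_identical(length(outs), nrow(parts))
  expect_identical(outs[[3]], enhance(fit, parts$image[[3]]))
  expect_error(enhance(fit, matrix(0.5, 10, 10)), "shape")
})

test_that("enhancer parameters scale ~4x when base filters double", {
  cfg8 <- tiny_config(enhancer_base_filters = 8L, epochs_enhancer = 1L)
  cfg16 <- tiny_config(enhancer_base_filters = 16L, epochs_enhancer = 1L)
  imgs <- list(matrix(runif(256), 16, 16), matrix(runif(256), 16, 16))
  f8 <- train_enhancer(list(input = imgs, target = imgs), cfg8, seed = 1)
  f16 <- train_enhancer(list(input = imgs, target = imgs), cfg16, seed = 1)
  ratio <- n_params(f16) / n_params(f8)
  expect_gt(ratio, 3.5)
  expect_lte(ratio, 4.0)
})

test_that("the quantifier fits constant labels and validates input", {
  withr::local_seed(47)
  imgs <- lapply(1:12, function(i) matrix(runif(16 * 16), 16, 16))
  # MAE has sign gradients, so Adam settles into an lr-sized wiggle around
  # the constant; a small rate and a longer schedule reach the floor
  cfg <- tiny_config(epochs_quantifier = 180L, batch_size = 4L,
                     augment = FALSE, learning_rate = 1e-3)
  fit <- train_quantifier(imgs, rep(0.5, 12), cfg, seed = 5)
  expect_lt(fit$history$loss[180], 0.01)
  expect_error(train_quantifier(imgs, rep(1.5, 12), cfg), "\\[0, 1\\]")
  expect_error(train_quantifier(imgs, rep(0.5, 3), cfg), "differ in length")
})

test_that("predicted counts are clipped and rescaled by count_max", {
  parts <- tiny_parts(1, seed = 48)
  cfg <- tiny_config()
  fit <- train_quantifier(parts$image, parts$count_norm, cfg, seed = 6)
  pred <- predict_count(fit, parts$image, count_max = 48)
  expect_identical(nrow(pred), nrow(parts))
  expect_true(all(pred$normalized >= 0 & pred$normalized <= 1))
  expect_equal(pred$count, pred$normalized * 48)
  # force negative raw output via the head bias: clipped to zero counts
  neg <- fit
  neg$P$fc_w[] <- 0
  neg$P$fc_b <- -0.02
  p0 <- predict_count(neg, parts$image[[1]])
  expect_identical(p0$normalized, 0)
  expect_identical(p0$count, 0)
  expect_error(predict_count(fit, matrix(0.5, 8, 8)), "shape")
})

test_that("the quantifier recovers counts from idealized enhanced images", {
  # scaled-down recovery run: train on enhancement targets, where counting
  # reduces to integrating bright blob area
  parts <- tiny_parts(10, seed = 49) # 60 parts at 40 x 48
  cfg <- train_config("desk", quantifier_filters = c(8L, 8L, 16L, 16L, 32L),
                      epochs_quantifier = 30L, augment = FALSE,
                      learning_rate = 3e-3, batch_size = 16L)
  fit <- train_quantifier(parts$target, parts$count_norm, cfg, seed = 7)
  expect_lt(fit$history$loss[30], 0.06) # < ~3 counts of 48
  # beats predicting the label mean
  base <- mean(abs(parts$count_norm - mean(parts$count_norm)))
  expect_lt(fit$history$loss[30], base)
})

test_that("tidy and glance summarize fitted networks", {
  parts <- tiny_parts(1, seed = 50)
  cfg <- tiny_config()
  fit <- train_enhancer(parts, cfg, seed = 8)
  h <- generics::tidy(fit)
  expect_named(h, c("epoch", "loss"))
  g <- generics::glance(fit)
  expect_identical(g$epochs, nrow(h))
  expect_identical(g$n_params, n_params(fit))
})
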