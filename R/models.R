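#' Training configuration and presets
#'
#' Bundles the optimization recipe and architecture sizes for both networks.
#' Two presets are provided:
#'
#' * `"paper"` — the full published recipe: Adam with learning rate 1e-4,
#'   batch size 45, 500 epochs for the enhancer and 300 for the quantifier,
#'   U-Net depth 4 with 64 base filters, quantifier filters
#'   (64, 64, 128, 128, 256), MSE/MAE losses, and augmentation by x/y flips,
#'   scaling 0.9--1.1 and rotation -15..15 degrees.
#' * `"desk"` — a reduced preset sized for a single CPU with this package's
#'   native training engine: depth 2 with 8 base filters, quantifier filters
#'   (8, 8, 16, 16, 32), learning rate 3e-3, batch 16, 20/25 epochs, same
#'   losses and augmentation. See the methods vignette for the sizing
#'   rationale.
#'
#' @param preset `"desk"` (default) or `"paper"`.
#' @param ... Named overrides of any field (e.g. `epochs_enhancer = 5`).
#' @return A list of class `pvs_train_config`.
#' @export
train_config <- function(preset = c("desk", "paper"), ...) {
  preset <- match.arg(preset)
  base <- list(
    preset = preset,
    optimizer = "adam",
    loss_enhancer = "mse",
    loss_quantifier = "mae",
    augment = TRUE,
    flip = TRUE,
    scale_range = c(0.9, 1.1),
    rotation_range = c(-15, 15),
    seed = NULL
  )
  cfg <- if (preset == "paper") {
    c(base, list(
      learning_rate = 1e-4, batch_size = 45L,
      epochs_enhancer = 500L, epochs_quantifier = 300L,
      enhancer_depth = 4L, enhancer_base_filters = 64L,
      quantifier_filters = c(64L, 64L, 128L, 128L, 256L)
    ))
  } else {
    c(base, list(
      learning_rate = 3e-3, batch_size = 16L,
      epochs_enhancer = 20L, epochs_quantifier = 25L,
      enhancer_depth = 2L, enhancer_base_filters = 8L,
      quantifier_filters = c(8L, 8L, 16L, 16L, 32L)
    ))
  }
  cfg <- modifyList(cfg, list(...))
  with(cfg, {
    stopifnot(learning_rate > 0, batch_size >= 1,
              epochs_enhancer >= 1, epochs_quantifier >= 1,
              enhancer_depth >= 1, enhancer_base_filters >= 1,
              length(quantifier_filters) == 5, all(quantifier_filters >= 1))
  })
  structure(cfg, class = "pvs_train_config")
}

#' Jointly augment a training pair
#'
#' Draws one geometric transform (independent x/y flips, isotropic scaling in
#' `scale_range`, rotation in `rotation_range` about the image centre) and
#' applies it identically to the input image and, when the target is an
#' image, to the target; scalar count labels pass through unchanged. Images
#' are resampled bilinearly with zero fill and clipped back to `[0, 1]`.
#'
#' @param input A `[0, 1]` image matrix.
#' @param target A matrix (transformed jointly) or a numeric scalar
#'   (passed through).
#' @param config A [train_config()] object (for the augmentation ranges).
#' @param draw Optional transform, as returned in `$draw`, to reapply the
#'   exact same geometry (e.g. to a mask).
#' @param interpolation `"bilinear"` (images) or `"nearest"` (masks).
#' @return List with `input`, `target` and the transform `draw`.
#' @export
augment_pair <- function(input, target, config = train_config(), draw = NULL,
                         interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  check_matrix(input, "input")
  if (is.null(draw)) {
    draw <- list(
      flip_x = isTRUE(config$flip) && runif(1) < 0.5,
      flip_y = isTRUE(config$flip) && runif(1) < 0.5,
      scale = runif(1, config$scale_range[1], config$scale_range[2]),
      angle = runif(1, config$rotation_range[1], config$rotation_range[2])
    )
  }
  bl <- interpolation == "bilinear"
  tf <- function(img) {
    out <- cpp_affine_resample(img, draw$angle, draw$scale,
                               draw$flip_x, draw$flip_y, bl, 0)
    pmin(pmax(out, 0), 1)
  }
  out_target <- if (is.matrix(target)) tf(target) else target
  list(input = tf(input), target = out_target, draw = draw)
}

# split shuffled indices into batches; a trailing singleton is folded into
# the previous batch (batch norm needs >= 2 samples)
make_batches <- function(idx, batch_size) {
  b <- split(idx, ceiling(seq_along(idx) / batch_size))
  n <- length(b)
  if (n > 1 && length(b[[n]]) == 1) {
    b[[n - 1]] <- c(b[[n - 1]], b[[n]])
    b[[n]] <- NULL
  }
  unname(b)
}

check_training_images <- function(images, depth = NULL) {
  d <- dim(images[[1]])
  for (im in images) {
    check_unit_image(im)
    if (!identical(dim(im), d)) stopf("training images must share one shape")
  }
  if (!is.null(depth) && any(d %% 2^depth != 0)) {
    stopf("input shape %dx%d is not divisible by 2^depth = %d",
          d[1], d[2], 2^depth)
  }
  d
}

#' Train the ePVS enhancement network
#'
#' Fits the U-Net image-to-image regressor that maps a normalized T2 part
#' image to its enhancement target (image plus ePVS mask, renormalized), by
#' minimizing mean squared error with Adam. The sigmoid output keeps
#' predictions in `[0, 1]`.
#'
#' @param pairs A `pvs_parts` tibble (uses the `image` and `target`
#'   list-columns) or a list with elements `input` and `target` (lists of
#'   matrices).
#' @param config A [train_config()] object.
#' @param seed Seed for initialization, batching and augmentation; defaults
#'   to `config$seed` or 1.
#' @return An object of class `pvs_enhancer` with the fitted parameters, the
#'   per-epoch training-loss history (see [tidy()]), the architecture and the
#'   config.
#' @export
train_enhancer <- function(pairs, config = train_config(), seed = NULL) {
  if (is.data.frame(pairs)) {
    stopifnot(all(c("image", "target") %in% names(pairs)))
    inputs <- pairs$image; targets <- pairs$target
  } else {
    inputs <- pairs$input; targets <- pairs$target
  }
  if (length(inputs) == 0) stopf("empty training set")
  if (length(inputs) != length(targets)) stopf("inputs and targets differ in length")
  d <- check_training_images(inputs, config$enhancer_depth)
  for (t in targets) {
    check_unit_image(t, "target")
    if (!identical(dim(t), d)) stopf("target shape differs from input shape")
  }
  arch <- list(depth = config$enhancer_depth,
               base_filters = config$enhancer_base_filters,
               in_shape = d)
  seed <- seed %||% config$seed %||% 1L
  local_seed(seed, {
    ini <- enhancer_init(arch)
    P <- ini$P; S <- ini$S
    opt <- adam_init(P)
    n <- length(inputs)
    losses <- numeric(config$epochs_enhancer)
    for (epoch in seq_len(config$epochs_enhancer)) {
      batches <- make_batches(sample.int(n), config$batch_size)
      bl <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        ids <- batches[[bi]]
        xs <- vector("list", length(ids)); ts <- xs
        for (q in seq_along(ids)) {
          if (isTRUE(config$augment)) {
            ap <- augment_pair(inputs[[ids[q]]], targets[[ids[q]]], config)
            xs[[q]] <- ap$input; ts[[q]] <- ap$target
          } else {
            xs[[q]] <- inputs[[ids[q]]]; ts[[q]] <- targets[[ids[q]]]
          }
        }
        x <- stack_images(xs); tt <- stack_images(ts)
        ctx <- new_ctx(P, S, training = TRUE)
        y <- enhancer_fwd(ctx, x, arch)
        diff <- y - tt
        bl[bi] <- mean(diff^2)
        enhancer_bwd(ctx, 2 * diff / length(diff), arch)
        S <- apply_bn_updates(S, ctx$bn_updates)
        st <- adam_step(P, ctx$grads, opt, config$learning_rate)
        P <- st$P; opt <- st$opt
      }
      losses[epoch] <- mean(bl)
    }
    structure(list(P = P, S = S, arch = arch,
                   history = tibble(epoch = seq_along(losses), loss = losses),
                   config = config, seed = seed, kind = "enhancer"),
              class = "pvs_enhancer")
  })
}

#' Apply a trained enhancer
#'
#' @param model A `pvs_enhancer` from [train_enhancer()].
#' @param image A matrix of the trained input shape, or a list of such
#'   matrices.
#' @param chunk Images per inference batch.
#' @return An enhanced `[0, 1]` matrix, or a list of them (order preserved).
#' @export
enhance <- function(model, image, chunk = 32L) {
  stopifnot(inherits(model, "pvs_enhancer"))
  single <- is.matrix(image)
  images <- if (single) list(image) else image
  for (im in images) {
    check_matrix(im)
    if (!identical(dim(im), model$arch$in_shape)) {
      stopf("image shape %s does not match the model input shape %s",
            paste(dim(im), collapse = "x"),
            paste(model$arch$in_shape, collapse = "x"))
    }
  }
  out <- vector("list", length(images))
  for (start in seq(1, length(images), by = chunk)) {
    ids <- start:min(start + chunk - 1, length(images))
    ctx <- new_ctx(model$P, model$S, training = FALSE)
    y <- enhancer_fwd(ctx, stack_images(images[ids]), model$arch)
    out[ids] <- unstack_images(y)
  }
  if (single) out[[1]] else out
}

#' Train the ePVS quantification network
#'
#' Fits the five-layer convolutional count regressor (batch norm + ReLU after
#' each convolution, 2x2 max-pooling after layers 2 and 4, global average
#' pooling, one linear output unit) on images with normalized count labels in
#' `[0, 1]`, minimizing mean absolute error with Adam.
#'
#' @param images List of `[0, 1]` image matrices (typically enhanced parts).
#' @param labels Numeric vector of normalized counts in `[0, 1]`.
#' @param config A [train_config()] object.
#' @param seed Seed (defaults to `config$seed` or 1).
#' @return An object of class `pvs_quantifier`.
#' @export
train_quantifier <- function(images, labels, config = train_config(),
                             seed = NULL) {
  if (is.data.frame(images)) {
    col <- if ("enhanced" %in% names(images)) "enhanced" else "image"
    images <- images[[col]]
  }
  if (length(images) == 0) stopf("empty training set")
  if (length(images) != length(labels)) stopf("images and labels differ in length")
  if (any(labels < 0 | labels > 1)) stopf("labels must be normalized to [0, 1]")
  d <- check_training_images(images, 2L) # two pooling stages
  arch <- list(conv_filters = as.integer(config$quantifier_filters),
               pool_after = c(2L, 4L), in_shape = d)
  seed <- seed %||% config$seed %||% 1L
  local_seed(seed, {
    ini <- quantifier_init(arch)
    P <- ini$P; S <- ini$S
    opt <- adam_init(P)
    n <- length(images)
    losses <- numeric(config$epochs_quantifier)
    for (epoch in seq_len(config$epochs_quantifier)) {
      batches <- make_batches(sample.int(n), config$batch_size)
      bl <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        ids <- batches[[bi]]
        xs <- vector("list", length(ids))
        for (q in seq_along(ids)) {
          xs[[q]] <- if (isTRUE(config$augment)) {
            augment_pair(images[[ids[q]]], labels[ids[q]], config)$input
          } else {
            images[[ids[q]]]
          }
        }
        x <- stack_images(xs)
        y <- labels[ids]
        ctx <- new_ctx(P, S, training = TRUE)
        pred <- quantifier_fwd(ctx, x, arch)
        bl[bi] <- mean(abs(pred - y))
        quantifier_bwd(ctx, sign(pred - y) / length(y), arch)
        S <- apply_bn_updates(S, ctx$bn_updates)
        st <- adam_step(P, ctx$grads, opt, config$learning_rate)
        P <- st$P; opt <- st$opt
      }
      losses[epoch] <- mean(bl)
    }
    structure(list(P = P, S = S, arch = arch,
                   history = tibble(epoch = seq_along(losses), loss = losses),
                   config = config, seed = seed, kind = "quantifier"),
              class = "pvs_quantifier")
  })
}

#' Predict ePVS counts with a trained quantifier
#'
#' The raw network output is clipped to `[0, 1]` and converted back to a
#' count by multiplying by the maximum count used for label normalization.
#'
#' @param model A `pvs_quantifier` from [train_quantifier()].
#' @param image A matrix or a list of matrices.
#' @param count_max Count denormalization constant (default 48).
#' @param chunk Images per inference batch.
#' @return A tibble with one row per image: `normalized` (clipped raw output)
#'   and `count` (`normalized * count_max`).
#' @export
predict_count <- function(model, image, count_max = 48, chunk = 64L) {
  stopifnot(inherits(model, "pvs_quantifier"))
  images <- if (is.matrix(image)) list(image) else image
  for (im in images) {
    check_matrix(im)
    if (!identical(dim(im), model$arch$in_shape)) {
      stopf("image shape %s does not match the model input shape %s",
            paste(dim(im), collapse = "x"),
            paste(model$arch$in_shape, collapse = "x"))
    }
  }
  raw <- numeric(length(images))
  for (start in seq(1, length(images), by = chunk)) {
    ids <- start:min(start + chunk - 1, length(images))
    ctx <- new_ctx(model$P, model$S, training = FALSE)
    raw[ids] <- quantifier_fwd(ctx, stack_images(images[ids]), model$arch)
  }
  normalized <- pmin(pmax(raw, 0), 1)
  tibble(normalized = normalized, count = denormalize_count(normalized, count_max))
}

#' @exportS3Method generics::tidy
tidy.pvs_enhancer <- function(x, ...) x$history

#' @exportS3Method generics::tidy
tidy.pvs_quantifier <- function(x, ...) x$history

#' @exportS3Method generics::glance
glance.pvs_enhancer <- function(x, ...) {
  tibble(kind = "enhancer", epochs = nrow(x$history),
         final_loss = x$history$loss[nrow(x$history)],
         n_params = n_params(x),
         depth = x$arch$depth, base_filters = x$arch$base_filters)
}

#' @exportS3Method generics::glance
glance.pvs_quantifier <- function(x, ...) {
  tibble(kind = "quantifier", epochs = nrow(x$history),
         final_loss = x$history$loss[nrow(x$history)],
         n_params = n_params(x),
         filters = paste(x$arch$conv_filters, collapse = ","))
}

#' @export
print.pvs_enhancer <- function(x, ...) {
  cat(sprintf("<pvs_enhancer> U-Net depth %d, base filters %d, %s input, %d params\n",
              x$arch$depth, x$arch$base_filters,
              paste(x$arch$in_shape, collapse = "x"), n_params(x)))
  cat(sprintf("  trained %d epochs, final MSE %.3g\n",
              nrow(x$history), x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' @export
print.pvs_quantifier <- function(x, ...) {
  cat(sprintf("<pvs_quantifier> conv filters (%s), %s input, %d params\n",
              paste(x$arch$conv_filters, collapse = ", "),
              paste(x$arch$in_shape, collapse = "x"), n_params(x)))
  cat(sprintf("  trained %d epochs, final MAE %.3g\n",
              nrow(x$history), x$history$loss[nrow(x$history)]))
  invisible(x)
}
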