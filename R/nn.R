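# Native neural-network engine. Parameters live in a flat named list `P`
# (arrays), batch-norm running statistics in `S`. Layer blocks are addressed
# by name prefix; gradients mirror `P`. All convolutions are 3x3 "same",
# pooling is 2x2 non-overlapping, upsampling is a 2x2 stride-2 transposed
# convolution. Everything is double precision and deterministic given the
# R RNG state (single-threaded kernels; GEMM via the linked BLAS).

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

init_cbr <- function(P, S, prefix, cin, cout, kh = 3L, kw = 3L) {
  P[[paste0(prefix, "_w")]] <- array(rnorm(kh * kw * cin * cout,
                                           sd = sqrt(2 / (kh * kw * cin))),
                                     dim = c(kh, kw, cin, cout))
  P[[paste0(prefix, "_b")]] <- numeric(cout)
  P[[paste0(prefix, "_g")]] <- rep(1, cout)
  P[[paste0(prefix, "_be")]] <- numeric(cout)
  S[[paste0(prefix, "_rm")]] <- numeric(cout)
  S[[paste0(prefix, "_rv")]] <- rep(1, cout)
  list(P = P, S = S)
}

init_upconv <- function(P, prefix, cin, cout) {
  P[[paste0(prefix, "_w")]] <- array(rnorm(4 * cout * cin, sd = sqrt(2 / cin)),
                                     dim = c(2L, 2L, cout, cin))
  P[[paste0(prefix, "_b")]] <- numeric(cout)
  P
}

# conv -> batch norm -> relu forward; `ctx` is an environment collecting
# caches and batch-norm statistics updates
cbr_fwd <- function(ctx, x, prefix) {
  P <- ctx$P
  z <- cpp_conv2d_fwd(x, P[[paste0(prefix, "_w")]], P[[paste0(prefix, "_b")]])
  if (ctx$training) {
    bn <- cpp_bn_fwd(z, P[[paste0(prefix, "_g")]], P[[paste0(prefix, "_be")]],
                     BN_EPS)
    ctx$bn_updates[[prefix]] <- list(mean = bn$mean, var = bn$var)
    y <- cpp_relu_fwd(bn$y)
    ctx$caches[[prefix]] <- list(x = x, z = z, mean = bn$mean, var = bn$var, y = y)
  } else {
    S <- ctx$S
    zn <- cpp_bn_infer(z, P[[paste0(prefix, "_g")]], P[[paste0(prefix, "_be")]],
                       S[[paste0(prefix, "_rm")]], S[[paste0(prefix, "_rv")]],
                       BN_EPS)
    y <- cpp_relu_fwd(zn)
  }
  y
}

cbr_bwd <- function(ctx, dy, prefix) {
  P <- ctx$P
  cache <- ctx$caches[[prefix]]
  dzn <- cpp_relu_bwd(dy, cache$y)
  bn <- cpp_bn_bwd(cache$z, dzn, P[[paste0(prefix, "_g")]],
                   cache$mean, cache$var, BN_EPS)
  cv <- cpp_conv2d_bwd(cache$x, P[[paste0(prefix, "_w")]], bn$dx)
  ctx$grads[[paste0(prefix, "_w")]] <- cv$dw
  ctx$grads[[paste0(prefix, "_b")]] <- cv$db
  ctx$grads[[paste0(prefix, "_g")]] <- bn$dgamma
  ctx$grads[[paste0(prefix, "_be")]] <- bn$dbeta
  cv$dx
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

new_ctx <- function(P, S, training) {
  ctx <- new.env(parent = emptyenv())
  ctx$P <- P
  ctx$S <- S
  ctx$training <- training
  ctx$caches <- list()
  ctx$bn_updates <- list()
  ctx$grads <- list()
  ctx
}

apply_bn_updates <- function(S, bn_updates) {
  for (prefix in names(bn_updates)) {
    u <- bn_updates[[prefix]]
    rm_ <- paste0(prefix, "_rm"); rv_ <- paste0(prefix, "_rv")
    S[[rm_]] <- (1 - BN_MOMENTUM) * S[[rm_]] + BN_MOMENTUM * u$mean
    S[[rv_]] <- (1 - BN_MOMENTUM) * S[[rv_]] + BN_MOMENTUM * u$var
  }
  S
}

# ---- U-Net enhancer ---------------------------------------------------------

enhancer_filters <- function(arch) arch$base_filters * 2^(seq_len(arch$depth) - 1)

enhancer_init <- function(arch) {
  P <- list(); S <- list()
  f <- enhancer_filters(arch)
  cin <- 1L
  for (l in seq_len(arch$depth)) {
    r <- init_cbr(P, S, sprintf("enc%d_c1", l), cin, f[l]); P <- r$P; S <- r$S
    r <- init_cbr(P, S, sprintf("enc%d_c2", l), f[l], f[l]); P <- r$P; S <- r$S
    cin <- f[l]
  }
  fb <- arch$base_filters * 2^arch$depth
  r <- init_cbr(P, S, "bot_c1", cin, fb); P <- r$P; S <- r$S
  r <- init_cbr(P, S, "bot_c2", fb, fb); P <- r$P; S <- r$S
  cup <- fb
  for (l in rev(seq_len(arch$depth))) {
    P <- init_upconv(P, sprintf("dec%d_up", l), cup, f[l])
    r <- init_cbr(P, S, sprintf("dec%d_c1", l), 2L * f[l], f[l]); P <- r$P; S <- r$S
    r <- init_cbr(P, S, sprintf("dec%d_c2", l), f[l], f[l]); P <- r$P; S <- r$S
    cup <- f[l]
  }
  P[["out_w"]] <- array(rnorm(arch$base_filters, sd = sqrt(1 / arch$base_filters)),
                        dim = c(1L, 1L, arch$base_filters, 1L))
  P[["out_b"]] <- 0
  list(P = P, S = S)
}

enhancer_fwd <- function(ctx, x, arch) {
  skips <- vector("list", arch$depth)
  for (l in seq_len(arch$depth)) {
    x <- cbr_fwd(ctx, x, sprintf("enc%d_c1", l))
    x <- cbr_fwd(ctx, x, sprintf("enc%d_c2", l))
    skips[[l]] <- x
    mp <- cpp_maxpool2_fwd(x)
    if (ctx$training) {
      ctx$caches[[sprintf("pool%d", l)]] <- list(idx = mp$idx,
                                                 H = dim(x)[1], W = dim(x)[2])
    }
    x <- mp$y
  }
  x <- cbr_fwd(ctx, x, "bot_c1")
  x <- cbr_fwd(ctx, x, "bot_c2")
  for (l in rev(seq_len(arch$depth))) {
    up <- cpp_upconv2_fwd(x, ctx$P[[sprintf("dec%d_up_w", l)]],
                          ctx$P[[sprintf("dec%d_up_b", l)]])
    if (ctx$training) {
      ctx$caches[[sprintf("up%d", l)]] <- list(x = x, nskip = dim(skips[[l]])[3])
    }
    x <- concat_channels(skips[[l]], up)
    x <- cbr_fwd(ctx, x, sprintf("dec%d_c1", l))
    x <- cbr_fwd(ctx, x, sprintf("dec%d_c2", l))
  }
  logits <- cpp_conv2d_fwd(x, ctx$P[["out_w"]], ctx$P[["out_b"]])
  if (ctx$training) ctx$caches[["out"]] <- list(x = x)
  y <- sigmoid(logits)
  if (ctx$training) ctx$caches[["sig"]] <- y
  y
}

enhancer_bwd <- function(ctx, dy, arch) {
  y <- ctx$caches[["sig"]]
  dlogits <- dy * y * (1 - y)
  cv <- cpp_conv2d_bwd(ctx$caches[["out"]]$x, ctx$P[["out_w"]], dlogits)
  ctx$grads[["out_w"]] <- cv$dw
  ctx$grads[["out_b"]] <- cv$db
  dx <- cv$dx
  dskips <- vector("list", arch$depth)
  for (l in seq_len(arch$depth)) {
    dx <- cbr_bwd(ctx, dx, sprintf("dec%d_c2", l))
    dcat <- cbr_bwd(ctx, dx, sprintf("dec%d_c1", l))
    upc <- ctx$caches[[sprintf("up%d", l)]]
    ns <- upc$nskip
    dskips[[l]] <- dcat[, , seq_len(ns), , drop = FALSE]
    dup <- dcat[, , ns + seq_len(dim(dcat)[3] - ns), , drop = FALSE]
    uv <- cpp_upconv2_bwd(upc$x, ctx$P[[sprintf("dec%d_up_w", l)]], dup)
    ctx$grads[[sprintf("dec%d_up_w", l)]] <- uv$dw
    ctx$grads[[sprintf("dec%d_up_b", l)]] <- uv$db
    dx <- uv$dx
  }
  dx <- cbr_bwd(ctx, dx, "bot_c2")
  dx <- cbr_bwd(ctx, dx, "bot_c1")
  for (l in rev(seq_len(arch$depth))) {
    pc <- ctx$caches[[sprintf("pool%d", l)]]
    dx <- cpp_maxpool2_bwd(dx, pc$idx, pc$H, pc$W)
    dx <- dx + dskips[[l]]
    dx <- cbr_bwd(ctx, dx, sprintf("enc%d_c2", l))
    dx <- cbr_bwd(ctx, dx, sprintf("enc%d_c1", l))
  }
  invisible(NULL)
}

# ---- quantifier -------------------------------------------------------------

quantifier_init <- function(arch) {
  P <- list(); S <- list()
  f <- arch$conv_filters
  cin <- 1L
  for (l in seq_along(f)) {
    r <- init_cbr(P, S, sprintf("q%d", l), cin, f[l]); P <- r$P; S <- r$S
    cin <- f[l]
  }
  cl <- f[length(f)]
  P[["fc_w"]] <- rnorm(cl, sd = sqrt(1 / cl))
  P[["fc_b"]] <- 0
  list(P = P, S = S)
}

quantifier_fwd <- function(ctx, x, arch) {
  nf <- length(arch$conv_filters)
  for (l in seq_len(nf)) {
    x <- cbr_fwd(ctx, x, sprintf("q%d", l))
    if (l %in% arch$pool_after) {
      mp <- cpp_maxpool2_fwd(x)
      if (ctx$training) {
        ctx$caches[[sprintf("qpool%d", l)]] <- list(idx = mp$idx,
                                                    H = dim(x)[1], W = dim(x)[2])
      }
      x <- mp$y
    }
  }
  g <- cpp_gap_fwd(x)                           # C x N
  if (ctx$training) ctx$caches[["gap"]] <- list(dim = dim(x), g = g)
  drop(crossprod(ctx$P[["fc_w"]], g)) + ctx$P[["fc_b"]]   # length-N vector
}

quantifier_bwd <- function(ctx, dpred, arch) {
  gc <- ctx$caches[["gap"]]
  ctx$grads[["fc_w"]] <- drop(gc$g %*% dpred)
  ctx$grads[["fc_b"]] <- sum(dpred)
  dg <- outer(ctx$P[["fc_w"]], dpred)           # C x N
  d <- gc$dim
  hw <- d[1] * d[2]
  dx <- array(rep(as.numeric(dg) / hw, each = hw), dim = d)
  for (l in rev(seq_along(arch$conv_filters))) {
    if (l %in% arch$pool_after) {
      pc <- ctx$caches[[sprintf("qpool%d", l)]]
      dx <- cpp_maxpool2_bwd(dx, pc$idx, pc$H, pc$W)
    }
    dx <- cbr_bwd(ctx, dx, sprintf("q%d", l))
  }
  invisible(NULL)
}

# ---- optimizer --------------------------------------------------------------

adam_init <- function(P) {
  list(m = purrr::map(P, ~ .x * 0), v = purrr::map(P, ~ .x * 0), t = 0L)
}

adam_step <- function(P, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    P[[nm]] <- P[[nm]] - lr * (opt$m[[nm]] / bc1) /
      (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(P = P, opt = opt)
}

#' Number of trainable parameters of a fitted network
#'
#' @param model A `pvs_enhancer` or `pvs_quantifier` object.
#' @return Integer count of trainable parameters (convolution and transposed
#'   convolution weights and biases, batch-norm scales and shifts, and the
#'   output head).
#' @export
n_params <- function(model) {
  stopifnot(is.list(model$P))
  sum(vapply(model$P, length, integer(1)))
}
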