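#' Classical enhancement baselines
#'
#' Three algorithmic enhancement methods that the learned enhancer is
#' compared against. Each takes a `[0, 1]` image and returns a `[0, 1]` image
#' of the same shape, renormalized by min-max so contrast-to-noise comparisons
#' use a common range. The source method citations give no parameter values,
#' so defaults here are tuned to small bright puncta (1--3 px) and are
#' configurable.
#'
#' * `tophat_enhance()`: white top-hat residual (image minus its morphological
#'   opening with a disk) added back to the image. The opening removes
#'   structures smaller than the disk, so the residual isolates small bright
#'   foci.
#' * `clahe_enhance()`: contrast-limited adaptive histogram equalization over
#'   a tile grid with bilinear blending of the per-tile mappings.
#' * `laplacian_enhance()`: unsharp-style edge boost, subtracting the
#'   weighted 4-neighbour discrete Laplacian.
#'
#' @param image Numeric matrix with values in `[0, 1]`.
#' @param radius Disk radius (px) of the top-hat structuring element, >= 1.
#' @param weight Positive Laplacian weight.
#' @param clip_limit Positive CLAHE clip limit, as a fraction of the tile
#'   pixel count per histogram bin.
#' @param tile_grid Integer (rows, cols) of the CLAHE tile grid.
#' @param n_bins Histogram resolution for CLAHE.
#' @return A `[0, 1]` matrix of the same shape as `image`.
#' @name baseline_enhance
NULL

#' @rdname baseline_enhance
#' @export
tophat_enhance <- function(image, radius = 3) {
  check_unit_image(image)
  if (radius < 1) stopf("`radius` must be >= 1")
  if (2 * radius + 1 > min(dim(image))) {
    stopf("structuring element (radius %d) larger than the image", radius)
  }
  opening <- cpp_morph_disk(cpp_morph_disk(image, as.integer(radius), FALSE),
                            as.integer(radius), TRUE)
  tophat <- image - opening
  minmax(image + tophat)
}

#' @rdname baseline_enhance
#' @export
clahe_enhance <- function(image, clip_limit = 0.01, tile_grid = c(8L, 8L),
                          n_bins = 256L) {
  check_unit_image(image)
  if (clip_limit <= 0) stopf("`clip_limit` must be positive")
  H <- nrow(image); W <- ncol(image)
  tr <- tile_grid[1]; tc <- tile_grid[2]
  if (tr > H || tc > W) stopf("tile grid %dx%d does not fit a %dx%d image",
                              tr, tc, H, W)
  row_br <- round(seq(0, H, length.out = tr + 1))
  col_br <- round(seq(0, W, length.out = tc + 1))
  bin_of <- function(v) pmin(n_bins, pmax(1L, 1L + as.integer(floor(v * n_bins))))

  # per-tile clipped-histogram CDF mappings (bin -> [0, 1])
  maps <- array(0, dim = c(n_bins, tr, tc))
  cy <- numeric(tr); cx <- numeric(tc)
  for (a in seq_len(tr)) {
    for (b in seq_len(tc)) {
      ii <- (row_br[a] + 1):row_br[a + 1]
      jj <- (col_br[b] + 1):col_br[b + 1]
      v <- image[ii, jj]
      h <- tabulate(bin_of(v), nbins = n_bins)
      clip <- max(1, clip_limit * length(v))
      excess <- sum(pmax(h - clip, 0))
      h <- pmin(h, clip) + excess / n_bins
      cdf <- cumsum(h) / sum(h)
      maps[, a, b] <- cdf
      cy[a] <- mean(ii) - 1
      cx[b] <- mean(jj) - 1
    }
  }

  # bilinear blending of the four surrounding tile mappings
  out <- matrix(0, H, W)
  bidx <- matrix(bin_of(image), H, W)
  ri <- findInterval(0:(H - 1), cy)            # tile strictly below each row
  ci <- findInterval(0:(W - 1), cx)
  for (i in seq_len(H)) {
    a0 <- max(1L, ri[i]); a1 <- min(tr, ri[i] + 1L)
    wa <- if (a1 == a0) 0 else ((i - 1) - cy[a0]) / (cy[a1] - cy[a0])
    for (b_ in seq_len(W)) {
      b0 <- max(1L, ci[b_]); b1 <- min(tc, ci[b_] + 1L)
      wb <- if (b1 == b0) 0 else ((b_ - 1) - cx[b0]) / (cx[b1] - cx[b0])
      bv <- bidx[i, b_]
      out[i, b_] <-
        (1 - wa) * (1 - wb) * maps[bv, a0, b0] +
        (1 - wa) * wb       * maps[bv, a0, b1] +
        wa       * (1 - wb) * maps[bv, a1, b0] +
        wa       * wb       * maps[bv, a1, b1]
    }
  }
  minmax(out)
}

#' @rdname baseline_enhance
#' @export
laplacian_enhance <- function(image, weight = 1) {
  check_unit_image(image)
  if (weight <= 0) stopf("`weight` must be positive")
  H <- nrow(image); W <- ncol(image)
  up <- image[c(1, seq_len(H - 1)), , drop = FALSE]     # replicate borders
  down <- image[c(seq_len(H - 1) + 1, H), , drop = FALSE]
  left <- image[, c(1, seq_len(W - 1)), drop = FALSE]
  right <- image[, c(seq_len(W - 1) + 1, W), drop = FALSE]
  lap <- up + down + left + right - 4 * image
  minmax(image - weight * lap)
}

#' Apply an enhancement method to a preprocessed cohort
#'
#' Adds an `enhanced` list-column to a `pvs_parts` tibble. `method = "none"`
#' passes the normalized image through; `"dl"` requires a trained enhancer
#' (see [train_enhancer()]).
#'
#' @param parts A `pvs_parts` tibble (see [preprocess_cohort()]).
#' @param method One of `"none"`, `"tophat"`, `"clahe"`, `"laplacian"`, `"dl"`.
#' @param model A trained `pvs_enhancer` (required for `method = "dl"`).
#' @param ... Passed on to the baseline function (e.g. `radius`).
#' @return `parts` with an added/replaced `enhanced` list-column.
#' @export
enhance_parts <- function(parts, method = c("none", "tophat", "clahe",
                                            "laplacian", "dl"),
                          model = NULL, ...) {
  method <- match.arg(method)
  stopifnot("image" %in% names(parts))
  enhanced <- switch(method,
    none = parts$image,
    tophat = purrr::map(parts$image, tophat_enhance, ...),
    clahe = purrr::map(parts$image, clahe_enhance, ...),
    laplacian = purrr::map(parts$image, laplacian_enhance, ...),
    dl = {
      if (is.null(model)) stopf("`model` is required for method = \"dl\"")
      enhance(model, parts$image)
    }
  )
  parts$enhanced <- enhanced
  parts
}
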