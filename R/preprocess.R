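#' Min-max normalize a raw image to the unit range
#'
#' Raw 16-bit scanner intensities are rescaled per image by
#' `(x - min) / (max - min)`. Per-image min-max (rather than dividing by the
#' nominal 16-bit maximum) is used because absolute scanner scaling varies
#' between acquisitions; a constant image maps to all zeros.
#'
#' @param raw Nonempty numeric matrix of nonnegative intensities.
#' @return A matrix of the same shape with values in `[0, 1]`.
#' @export
normalize_intensity <- function(raw) {
  check_matrix(raw, "raw")
  if (min(raw) < 0) stopf("`raw` must be nonnegative")
  minmax(raw * 1.0)
}

#' Crop one hemisphere ROI from a slice and resize it
#'
#' Zeroes everything outside the ROI mask, splits the mask's bounding region
#' at its horizontal midpoint into a left and a right hemisphere, crops the
#' requested hemisphere to its bounding box, and bilinearly resamples the crop
#' to `out_shape` (default 80 x 96 = rows x cols).
#'
#' @param slice Numeric matrix (one axial slice).
#' @param roi_mask Binary matrix of the same shape (basal-ganglia ROI).
#' @param hemisphere `"left"` or `"right"`. Image-coordinate convention:
#'   "left" is the lower-column half of the ROI bounding region.
#' @param out_shape Output (rows, cols).
#' @param context Optional label (e.g. subject/slice) used in error messages.
#' @return A numeric matrix of shape `out_shape`.
#' @export
crop_and_resize <- function(slice, roi_mask, hemisphere = c("left", "right"),
                            out_shape = c(80L, 96L), context = NULL) {
  hemisphere <- match.arg(hemisphere)
  check_matrix(slice, "slice")
  check_binary_mask(roi_mask, "roi_mask")
  check_same_shape(slice, roi_mask, "slice", "roi_mask")
  where <- if (is.null(context)) hemisphere else paste(context, hemisphere)
  if (sum(roi_mask) == 0) stopf("empty ROI mask (%s)", where)
  cols <- which(colSums(roi_mask) > 0)
  mid <- (min(cols) + max(cols)) / 2
  keep_cols <- if (hemisphere == "left") {
    seq_len(floor(mid))
  } else {
    seq(ceiling(mid + 1e-9), ncol(roi_mask))
  }
  hemi_mask <- roi_mask
  hemi_mask[, setdiff(seq_len(ncol(roi_mask)), keep_cols)] <- 0L
  if (sum(hemi_mask) == 0) stopf("empty hemisphere ROI (%s)", where)
  rr <- range(which(rowSums(hemi_mask) > 0))
  cc <- range(which(colSums(hemi_mask) > 0))
  crop <- slice[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE] *
    hemi_mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  cpp_resize(crop, out_shape[1], out_shape[2], TRUE)
}

#' Construct the enhancement regression target
#'
#' The learning target for the enhancement network is built by element-wise
#' adding the binary ePVS mask to the normalized image and renormalizing to
#' `[0, 1]`: masked pixels are pushed to the top of the intensity range while
#' background structure is compressed but preserved. With an empty mask the
#' image is returned unchanged.
#'
#' @param image Numeric matrix with values in `[0, 1]`.
#' @param mask Binary matrix of the same shape.
#' @return A matrix in `[0, 1]`, same shape.
#' @examples
#' img <- matrix(0.5, 4, 4); m <- matrix(0L, 4, 4); m[2, 2] <- 1L
#' t <- make_enhancement_target(img, m)
#' t[2, 2] # 1
#' @export
make_enhancement_target <- function(image, mask) {
  check_unit_image(image)
  check_binary_mask(mask)
  check_same_shape(image, mask)
  if (sum(mask) == 0) return(image)
  minmax(image + mask)
}

#' Normalize / denormalize an ePVS count
#'
#' Counts are mapped to `[0, 1]` for regression by dividing by the maximum
#' count observed in the cohort (default 48); predictions are mapped back by
#' multiplying, after clipping the network output to `[0, 1]`. The round trip
#' is exact for integer counts.
#'
#' @param count Integer count(s) in `0..count_max`.
#' @param value Normalized value(s); clipped to `[0, 1]`.
#' @param count_max Maximum count (default 48).
#' @param clip For `normalize_count`: if `TRUE`, counts above `count_max` are
#'   clipped instead of raising an error (default `FALSE`).
#' @return Numeric vector.
#' @export
normalize_count <- function(count, count_max = 48, clip = FALSE) {
  if (any(count < 0)) stopf("`count` must be nonnegative")
  if (any(count > count_max)) {
    if (!clip) stopf("count %s exceeds `count_max` = %d",
                     max(count), count_max)
    count <- pmin(count, count_max)
  }
  count / count_max
}

#' @rdname normalize_count
#' @export
denormalize_count <- function(value, count_max = 48) {
  pmin(pmax(value, 0), 1) * count_max
}

#' Standardize a phantom cohort for training
#'
#' Applies the preprocessing pipeline to each part of a [generate_cohort()]
#' tibble: bilinear resize of the raw image to `out_shape`, nearest-neighbour
#' resize (and re-binarization) of the mask, per-image min-max normalization,
#' enhancement-target construction, and count normalization. The stored count
#' (pre-resize truth) is kept as the label even if resizing merges puncta.
#'
#' @param cohort A `pvs_cohort` tibble (or any tibble with `raw`, `mask`,
#'   `count` columns).
#' @param out_shape Target (rows, cols), default `c(80, 96)`.
#' @param count_max Count normalization constant (default 48).
#' @return A tibble of class `pvs_parts` with list-columns `image`, `mask`,
#'   `target` (all `out_shape`, values in `[0, 1]`) and column `count_norm`.
#' @export
preprocess_cohort <- function(cohort, out_shape = c(80L, 96L), count_max = 48) {
  stopifnot(all(c("raw", "mask", "count") %in% names(cohort)))
  parts <- dplyr::mutate(as_tibble(cohort),
    image = purrr::map(.data$raw, function(r) {
      normalize_intensity(cpp_resize(r * 1.0, out_shape[1], out_shape[2], TRUE))
    }),
    mask = purrr::map(.data$mask, function(m) {
      rm <- cpp_resize(m * 1.0, out_shape[1], out_shape[2], FALSE)
      matrix(as.integer(rm >= 0.5), out_shape[1], out_shape[2])
    }),
    target = purrr::map2(.data$image, .data$mask, make_enhancement_target),
    count_norm = normalize_count(.data$count, count_max)
  )
  parts <- dplyr::select(parts, -dplyr::any_of("raw"))
  structure(parts,
            out_shape = as.integer(out_shape), count_max = count_max,
            class = unique(c("pvs_parts", class(parts))))
}
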