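#' Parameters of the synthetic ePVS phantom
#'
#' Describes the stated world the phantom emulates: per-part 2D crops of the
#' basal ganglia on T2-weighted MRI, with small hyperintense puncta (the ePVS)
#' on a textured tissue background. Defaults follow the study cohort where the
#' source states them: the grade distribution is the empirical rating
#' histogram of 456 basal-ganglia part images (skewed toward grades 1--2), and
#' the maximum per-part count is 48. Geometry and intensity defaults are
#' plausible choices for 3T T2 at ~0.57 mm in-plane resolution (see the
#' methods vignette): puncta are anti-aliased ellipses of radius 1.5--3.5 px
#' with eccentricity up to 2:1, the background is a smoothed Gaussian random
#' field plus i.i.d. Gaussian noise, and parts are emitted at 120 x 140 so
#' that the later resize to 80 x 96 is a real resampling step.
#'
#' @param part_shape Integer (rows, cols) of an emitted part image.
#' @param grade_probs Five nonnegative weights over grades 0--4 (normalized
#'   internally). Default: the 456-image rating histogram (4, 244, 138, 55, 15).
#' @param count_max Maximum per-part ePVS count (grade-4 counts are drawn
#'   uniformly from 41..`count_max`). Must be at least 40.
#' @param puncta_radius_range Min/max punctum radius in pixels (min >= 1).
#' @param puncta_intensity_boost Punctum brightness as a fraction of the raw
#'   dynamic range.
#' @param tissue_mean,tissue_sd Mean and spatial standard deviation of the
#'   tissue texture, in raw 16-bit units.
#' @param noise_sd Standard deviation of i.i.d. additive noise (raw units).
#' @param texture_scale Gaussian smoothing length (px) of the tissue texture.
#' @param bit_depth Bits per raw intensity value (default 16).
#' @param max_place_retries Bounded rejection-sampling retries per punctum.
#' @return A list of class `pvs_phantom_params`.
#' @export
phantom_params <- function(part_shape = c(120L, 140L),
                           grade_probs = c(4, 244, 138, 55, 15) / 456,
                           count_max = 48L,
                           puncta_radius_range = c(1.5, 3.5),
                           puncta_intensity_boost = 0.25,
                           tissue_mean = 20000,
                           tissue_sd = 3000,
                           noise_sd = 800,
                           texture_scale = 6,
                           bit_depth = 16L,
                           max_place_retries = 1000L) {
  if (length(part_shape) != 2 || any(part_shape < 16)) {
    stopf("`part_shape` must be two integers >= 16")
  }
  if (length(grade_probs) != 5 || any(grade_probs < 0) || anyNA(grade_probs)) {
    stopf("`grade_probs` must be 5 nonnegative weights")
  }
  if (sum(grade_probs) <= 0) {
    stopf("`grade_probs` must not be all zero", class = "pvscade_invalid_parameter")
  }
  if (count_max < 40) stopf("`count_max` must be >= 40 so that grade 4 is reachable")
  if (puncta_radius_range[1] < 1 || diff(puncta_radius_range) < 0) {
    stopf("`puncta_radius_range` must be increasing with min >= 1 pixel")
  }
  structure(list(
    part_shape = as.integer(part_shape),
    grade_probs = grade_probs / sum(grade_probs),
    count_max = as.integer(count_max),
    puncta_radius_range = puncta_radius_range,
    puncta_intensity_boost = puncta_intensity_boost,
    tissue_mean = tissue_mean,
    tissue_sd = tissue_sd,
    noise_sd = noise_sd,
    texture_scale = texture_scale,
    bit_depth = as.integer(bit_depth),
    max_place_retries = as.integer(max_place_retries)
  ), class = "pvs_phantom_params")
}

#' Draw per-part ePVS counts from the grade-stratified distribution
#'
#' A count is drawn by first drawing a Potter grade from `grade_probs`, then a
#' uniform integer within that grade's count bracket (grade 0: 0; grade 1:
#' 1--10; grade 2: 11--20; grade 3: 21--40; grade 4: 41--`count_max`). Uses
#' the current RNG stream; seed with [set.seed()] or via [generate_cohort()].
#'
#' @param params A [phantom_params()] object.
#' @param n Number of counts to draw.
#' @return Integer vector of counts in `0..count_max`.
#' @export
sample_count <- function(params = phantom_params(), n = 1L) {
  stopifnot(inherits(params, "pvs_phantom_params"))
  grades <- sample.int(5L, n, replace = TRUE, prob = params$grade_probs) - 1L
  if (any(grades == 4L) && params$count_max < 41) {
    stopf("grade 4 drawn but `count_max` < 41")
  }
  lo <- c(0L, 1L, 11L, 21L, 41L)[grades + 1L]
  hi <- c(0L, 10L, 20L, 40L, params$count_max)[grades + 1L]
  lo + as.integer(floor(runif(n) * (hi - lo + 1)))
}

# place `count` non-overlapping ellipse centres by bounded rejection sampling
place_puncta <- function(count, params) {
  H <- params$part_shape[1]; W <- params$part_shape[2]
  rr <- params$puncta_radius_range
  out <- vector("list", count)
  if (count == 0) return(out)
  placed_y <- numeric(0); placed_x <- numeric(0); placed_ext <- numeric(0)
  for (p in seq_len(count)) {
    ok <- FALSE
    for (try in seq_len(params$max_place_retries)) {
      r <- runif(1, rr[1], rr[2])
      ecc <- runif(1, 1, 2)
      a <- r * sqrt(ecc)        # major semi-axis
      b <- r / sqrt(ecc)        # minor semi-axis
      phi <- runif(1, 0, pi)
      margin <- a + 2
      cy <- runif(1, margin, H - 1 - margin)
      cx <- runif(1, margin, W - 1 - margin)
      if (length(placed_y)) {
        d <- sqrt((placed_y - cy)^2 + (placed_x - cx)^2)
        if (any(d < placed_ext + a + 2.5)) next
      }
      placed_y <- c(placed_y, cy); placed_x <- c(placed_x, cx)
      placed_ext <- c(placed_ext, a)
      out[[p]] <- list(cy = cy, cx = cx, a = a, b = b, r = r, phi = phi)
      ok <- TRUE
      break
    }
    if (!ok) {
      stopf("could not place %d non-overlapping puncta in a %dx%d part after %d retries",
            count, H, W, params$max_place_retries,
            class = "pvscade_placement_error")
    }
  }
  out
}

#' Render one phantom part image
#'
#' Draws a textured tissue background (smoothed Gaussian random field plus
#' i.i.d. noise), places `count` non-overlapping anti-aliased elliptical
#' puncta brightened by `puncta_intensity_boost` of the dynamic range, and
#' returns the integer raw image together with the exact binary punctum mask.
#' The mask has exactly `count` 8-connected components, so the stored count is
#' unambiguous ground truth.
#'
#' @param count Number of puncta (>= 0).
#' @param params A [phantom_params()] object.
#' @return A list with integer matrices `raw` (values in `[0, 2^bit_depth)`)
#'   and `mask` (0/1).
#' @export
render_part <- function(count, params = phantom_params()) {
  stopifnot(inherits(params, "pvs_phantom_params"))
  if (length(count) != 1 || is.na(count) || count < 0) {
    stopf("`count` must be a single nonnegative integer")
  }
  H <- params$part_shape[1]; W <- params$part_shape[2]
  field <- cpp_gauss_blur(matrix(rnorm(H * W), H, W), params$texture_scale)
  field <- field / sd(field)
  raw <- params$tissue_mean + params$tissue_sd * field +
    matrix(rnorm(H * W, sd = params$noise_sd), H, W)

  mask <- matrix(0L, H, W)
  top <- (2^params$bit_depth - 1)
  boost <- params$puncta_intensity_boost * top
  for (pt in place_puncta(count, params)) {
    win <- ceiling(pt$a) + 2L
    ii <- max(1, floor(pt$cy) - win):min(H, ceiling(pt$cy) + win)
    jj <- max(1, floor(pt$cx) - win):min(W, ceiling(pt$cx) + win)
    dy <- (ii - 1) - pt$cy
    dx <- (jj - 1) - pt$cx
    u <- outer(dy * cos(pt$phi), dx * sin(pt$phi), "+")  # rotated coords
    v <- outer(-dy * sin(pt$phi), dx * cos(pt$phi), "+")
    q <- sqrt((u / pt$a)^2 + (v / pt$b)^2)
    cov <- pmin(1, pmax(0, (1 - q) * pt$r + 0.5))        # ~1 px soft edge
    raw[ii, jj] <- raw[ii, jj] + boost * cov
    mask[ii, jj] <- pmax(mask[ii, jj], as.integer(cov >= 0.5))
  }
  raw <- matrix(as.integer(round_half_up(pmin(pmax(raw, 0), top))), H, W)
  list(raw = raw, mask = mask)
}

#' Generate a seeded synthetic cohort
#'
#' Emits `n_subjects` subjects, each with six part images (three axial slices
#' x left/right hemisphere), with grade-stratified counts, exact puncta
#' masks, per-part Potter grades, and the subject-level grade as the maximum
#' of the six part grades. Regeneration with the same seed is bit-identical.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param params A [phantom_params()] object.
#' @param seed Integer seed controlling all randomness of the cohort.
#' @return A tibble of class `pvs_cohort` with one row per part: `subject_id`,
#'   `slice_index`, `hemisphere`, `count`, `grade`, `subject_grade`, and
#'   list-columns `raw` (integer matrix) and `mask` (binary matrix).
#' @examples
#' ph <- phantom_params(part_shape = c(60L, 70L))
#' cohort <- generate_cohort(2, ph, seed = 7)
#' dplyr::count(cohort, subject_id)
#' @export
generate_cohort <- function(n_subjects, params = phantom_params(), seed = 1L) {
  stopifnot(inherits(params, "pvs_phantom_params"))
  if (n_subjects < 1) stopf("`n_subjects` must be >= 1")
  rows <- local_seed(seed, {
    purrr::map(seq_len(n_subjects), function(s) {
      id <- sprintf("S%03d", s)
      grid <- tidyr::expand_grid(slice_index = 1:3,
                                 hemisphere = c("left", "right"))
      counts <- sample_count(params, nrow(grid))
      parts <- purrr::map(counts, render_part, params = params)
      dplyr::mutate(grid,
        subject_id = id,
        count = as.integer(counts),
        grade = grade_from_count(counts),
        raw = purrr::map(parts, "raw"),
        mask = purrr::map(parts, "mask")
      )
    })
  })
  cohort <- dplyr::bind_rows(rows)
  cohort <- dplyr::mutate(
    dplyr::group_by(cohort, .data$subject_id),
    subject_grade = subject_grade(.data$grade)
  )
  cohort <- dplyr::ungroup(cohort)
  cohort <- dplyr::select(cohort, "subject_id", "slice_index", "hemisphere",
                          "count", "grade", "subject_grade", "raw", "mask")
  structure(cohort, params = params, seed = seed,
            class = c("pvs_cohort", class(cohort)))
}

#' Render a whole axial slice with a two-hemisphere ROI mask
#'
#' Convenience emitter for exercising ROI cropping: a larger slice-sized
#' canvas containing two elliptical basal-ganglia-like ROI regions (left and
#' right), puncta placed only inside the ROIs, and the corresponding ROI and
#' ePVS masks.
#'
#' @param counts Integer vector `c(left, right)` of puncta per hemisphere.
#' @param params A [phantom_params()] object (`part_shape` is reused as the
#'   per-hemisphere ROI extent).
#' @param slice_shape (rows, cols) of the emitted slice.
#' @return List with matrices `raw`, `roi_mask`, `pvs_mask`.
#' @export
render_slice <- function(counts = c(5L, 5L), params = phantom_params(),
                         slice_shape = c(240L, 320L)) {
  H <- slice_shape[1]; W <- slice_shape[2]
  field <- cpp_gauss_blur(matrix(rnorm(H * W), H, W), params$texture_scale)
  field <- field / sd(field)
  top <- 2^params$bit_depth - 1
  raw <- params$tissue_mean + params$tissue_sd * field +
    matrix(rnorm(H * W, sd = params$noise_sd), H, W)
  roi <- matrix(0L, H, W)
  pvs <- matrix(0L, H, W)
  ry <- H / 4.5; rx <- W / 7
  centers <- list(left = c(H / 2, W * 0.3), right = c(H / 2, W * 0.7))
  for (side in c("left", "right")) {
    ctr <- centers[[side]]
    yy <- matrix(seq_len(H) - 1 - ctr[1], H, W)
    xx <- matrix(seq_len(W) - 1 - ctr[2], H, W, byrow = TRUE)
    inside <- (yy / ry)^2 + (xx / rx)^2 <= 1
    roi[inside] <- 1L
    n <- counts[[if (side == "left") 1 else 2]]
    placed <- 0L
    tries <- 0L
    while (placed < n && tries < params$max_place_retries * n) {
      tries <- tries + 1L
      r <- runif(1, params$puncta_radius_range[1], params$puncta_radius_range[2])
      cy <- runif(1, ctr[1] - ry, ctr[1] + ry)
      cx <- runif(1, ctr[2] - rx, ctr[2] + rx)
      if (((cy - ctr[1]) / (ry - r - 2))^2 + ((cx - ctr[2]) / (rx - r - 2))^2 > 1) next
      ii <- max(1, floor(cy - r - 1)):min(H, ceiling(cy + r + 1))
      jj <- max(1, floor(cx - r - 1)):min(W, ceiling(cx + r + 1))
      if (any(pvs[max(1, min(ii) - 2):min(H, max(ii) + 2),
                  max(1, min(jj) - 2):min(W, max(jj) + 2)] > 0)) next
      d <- sqrt(outer(((ii - 1) - cy)^2, ((jj - 1) - cx)^2, "+"))
      cov <- pmin(1, pmax(0, (r - d) + 0.5))
      raw[ii, jj] <- raw[ii, jj] + params$puncta_intensity_boost * top * cov
      pvs[ii, jj] <- pmax(pvs[ii, jj], as.integer(cov >= 0.5))
      placed <- placed + 1L
    }
    if (placed < n) {
      stopf("could not place %d puncta in the %s ROI", n, side,
            class = "pvscade_placement_error")
    }
  }
  raw <- matrix(as.integer(round_half_up(pmin(pmax(raw, 0), top))), H, W)
  list(raw = raw, roi_mask = roi, pvs_mask = pvs)
}

#' Count 8-connected components of a binary mask
#'
#' Standard connected-component labeling; used as the oracle tying a stored
#' phantom count to its mask.
#'
#' @param mask Binary matrix.
#' @return List with `labels` (integer matrix) and `n` (component count).
#' @export
label_components <- function(mask) {
  check_binary_mask(mask)
  lab <- cpp_label_components(matrix(as.integer(mask), nrow(mask), ncol(mask)))
  list(labels = lab, n = max(lab))
}
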