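#' Contrast-to-noise ratio of an ePVS region
#'
#' `CNR = |mu_signal1 - mu_signal2| / sigma_noise`, where `mu_signal1` is the
#' mean intensity inside the ePVS region, `mu_signal2` the mean intensity in
#' the surrounding area, and `sigma_noise` the standard deviation measured in
#' a background region of the slice. The three masks must be nonempty and
#' pairwise disjoint.
#'
#' @param image Numeric matrix.
#' @param signal_mask,surround_mask,background_mask Binary matrices of the
#'   same shape as `image`.
#' @return A one-row tibble: `mu_signal1`, `mu_signal2`, `sigma_noise`, `cnr`.
#' @examples
#' img <- matrix(0.3, 8, 8)
#' sig <- sur <- bg <- matrix(0L, 8, 8)
#' sig[2, 2] <- 1L; img[2, 2] <- 0.8
#' sur[4, ] <- 1L
#' bg[7:8, ] <- 1L; img[7:8, ] <- 0.3 + rep(c(-0.01, 0.01), each = 8)
#' compute_cnr(img, sig, sur, bg)
#' @export
compute_cnr <- function(image, signal_mask, surround_mask, background_mask) {
  check_matrix(image)
  for (m in list(signal_mask, surround_mask, background_mask)) {
    check_binary_mask(m)
    check_same_shape(image, m)
    if (sum(m) == 0) stopf("all three CNR masks must be nonempty")
  }
  if (any(signal_mask & surround_mask) || any(signal_mask & background_mask) ||
      any(surround_mask & background_mask)) {
    stopf("CNR masks must be pairwise disjoint")
  }
  mu1 <- mean(image[signal_mask == 1])
  mu2 <- mean(image[surround_mask == 1])
  sigma <- sd(image[background_mask == 1])
  if (!is.finite(sigma) || sigma == 0) {
    stopf("sigma_noise is zero: CNR undefined")
  }
  tibble(mu_signal1 = mu1, mu_signal2 = mu2, sigma_noise = sigma,
         cnr = abs(mu1 - mu2) / sigma)
}

#' Derive CNR regions from an ePVS mask
#'
#' The source protocol names the three CNR regions but does not define their
#' geometry; this package uses: signal = the ePVS mask itself; surround = a
#' ring obtained by dilating the mask by `ring_radius` pixels and removing
#' the mask; background = a `frame_width`-pixel frame at the part border,
#' excluding any dilated ePVS tissue.
#'
#' @param mask Binary ePVS mask.
#' @param ring_radius Dilation radius (px) of the surround ring.
#' @param frame_width Width (px) of the border frame used for noise.
#' @return List of binary matrices `signal`, `surround`, `background`.
#' @export
cnr_masks <- function(mask, ring_radius = 3L, frame_width = 8L) {
  check_binary_mask(mask)
  H <- nrow(mask); W <- ncol(mask)
  dil <- cpp_morph_disk(mask * 1.0, as.integer(ring_radius), TRUE)
  dil <- matrix(as.integer(dil >= 0.5), H, W)
  surround <- dil * (1L - mask)
  frame <- matrix(0L, H, W)
  w <- min(frame_width, floor(min(H, W) / 2))
  frame[c(seq_len(w), H - seq_len(w) + 1), ] <- 1L
  frame[, c(seq_len(w), W - seq_len(w) + 1)] <- 1L
  background <- frame * (1L - dil)
  list(signal = mask, surround = surround, background = background)
}

#' CNR of one part image given its ePVS mask
#'
#' Convenience wrapper deriving the three regions with [cnr_masks()] and
#' calling [compute_cnr()]. Returns `NA` CNR (with a reason) instead of
#' failing when the part has no ePVS.
#'
#' @inheritParams cnr_masks
#' @param image Numeric part image.
#' @return A one-row tibble as in [compute_cnr()] (NA fields if `mask` is
#'   empty).
#' @export
part_cnr <- function(image, mask, ring_radius = 3L, frame_width = 8L) {
  if (sum(mask) == 0) {
    return(tibble(mu_signal1 = NA_real_, mu_signal2 = NA_real_,
                  sigma_noise = NA_real_, cnr = NA_real_))
  }
  m <- cnr_masks(mask, ring_radius, frame_width)
  compute_cnr(image, m$signal, m$surround, m$background)
}

#' Assign subjects to cross-validation folds
#'
#' Subject-level partition into `k` folds by a seeded uniform shuffle (no
#' grade stratification): all six parts of a subject share a fold, so no
#' subject ever appears in both a training and a test set. Fold sizes differ
#' by at most one; 76 subjects at `k = 4` give folds of 19.
#'
#' @param subject_ids Character vector of unique subject identifiers.
#' @param k Number of folds (default 4).
#' @param seed Shuffle seed.
#' @return A tibble of class `pvs_folds` with columns `subject_id`, `fold`.
#' @export
make_folds <- function(subject_ids, k = 4L, seed = 1L) {
  subject_ids <- unique(subject_ids)
  if (k < 2) stopf("`k` must be >= 2")
  if (length(subject_ids) < k) {
    stopf("need at least k = %d subjects (got %d)", k, length(subject_ids))
  }
  shuffled <- local_seed(seed, sample(subject_ids))
  plan <- tibble(subject_id = shuffled,
                 fold = rep_len(seq_len(k), length(shuffled)))
  plan <- dplyr::arrange(plan, .data$subject_id)
  structure(plan, k = as.integer(k), seed = seed,
            class = c("pvs_folds", class(plan)))
}

# pooled + per-fold metrics from a prediction table
summarize_predictions <- function(pred) {
  subj <- pred |>
    dplyr::group_by(.data$subject_id, .data$fold) |>
    dplyr::summarise(
      truth_grade = max(.data$truth_grade),
      pred_grade = max(.data$pred_grade),
      .groups = "drop"
    )
  pooled <- tibble(
    fold = NA_integer_,
    n_images = nrow(pred),
    mae = mae(pred$truth_count, pred$pred_count),
    mse = mse(pred$truth_count, pred$pred_count),
    image_accuracy = grade_accuracy(pred$truth_grade, pred$pred_grade),
    subject_accuracy = grade_accuracy(subj$truth_grade, subj$pred_grade),
    mean_cnr = if (all(is.na(pred$cnr))) NA_real_ else
      mean(pred$cnr, na.rm = TRUE)
  )
  per_fold <- pred |>
    dplyr::group_by(.data$fold) |>
    dplyr::summarise(
      n_images = dplyr::n(),
      mae = mae(.data$truth_count, .data$pred_count),
      mse = mse(.data$truth_count, .data$pred_count),
      image_accuracy = grade_accuracy(.data$truth_grade, .data$pred_grade),
      mean_cnr = if (all(is.na(.data$cnr))) NA_real_ else
        mean(.data$cnr, na.rm = TRUE),
      .groups = "drop"
    )
  list(pooled = pooled, per_fold = per_fold, subjects = subj)
}

#' Run the full cascade under subject-level cross-validation
#'
#' For each fold: (for `method = "dl"`) train the enhancement U-Net on the
#' training subjects' (image, target) pairs and enhance both partitions with
#' it; (for baseline methods) apply the deterministic enhancement; then train
#' the count quantifier on the training subjects' enhanced images and predict
#' the held-out subjects. Test predictions are pooled across folds into MAE,
#' image- and subject-level grade accuracy, ICC (image and subject level),
#' and mean CNR of the enhanced test images. No subject ever contributes to
#' both training and evaluation of the models applied to it.
#'
#' @param parts A `pvs_parts` tibble from [preprocess_cohort()].
#' @param method Enhancement method: `"none"`, `"tophat"`, `"clahe"`,
#'   `"laplacian"` or `"dl"`.
#' @param config A [train_config()] object.
#' @param k Number of folds (default 4).
#' @param seed Seed controlling fold assignment and all training randomness.
#' @param count_max Count scale (defaults to the `pvs_parts` attribute, or 48).
#' @return An object of class `pvs_eval`: prediction table (`$predictions`),
#'   fold plan, pooled and per-fold metrics, ICCs, and training histories.
#'   Use [glance()] for the one-row summary and [tidy()] for per-fold rows.
#' @export
run_cross_validation <- function(parts,
                                 method = c("none", "tophat", "clahe",
                                            "laplacian", "dl"),
                                 config = train_config(), k = 4L, seed = 1L,
                                 count_max = NULL) {
  method <- match.arg(method)
  stopifnot(all(c("subject_id", "image", "mask", "count", "grade") %in%
                  names(parts)))
  if (anyNA(parts$count) || anyNA(parts$grade)) stopf("missing labels")
  count_max <- count_max %||% attr(parts, "count_max") %||% 48
  folds <- make_folds(unique(parts$subject_id), k = k, seed = seed)
  parts <- dplyr::left_join(as_tibble(parts), folds, by = "subject_id")

  if (method %in% c("tophat", "clahe", "laplacian")) {
    # deterministic per-image filters: no leakage possible, apply once
    parts <- enhance_parts(parts, method)
  } else if (method == "none") {
    parts$enhanced <- parts$image
  }

  histories <- list()
  preds <- vector("list", k)
  fold_subjects <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- parts[parts$fold != f, ]
    te <- parts[parts$fold == f, ]
    fold_subjects[[f]] <- list(train = unique(tr$subject_id),
                               test = unique(te$subject_id))
    fold_seed <- (seed + 7919L * f) %% .Machine$integer.max
    if (method == "dl") {
      enh <- train_enhancer(tr, config, seed = fold_seed)
      tr$enhanced <- enhance(enh, tr$image)
      te$enhanced <- enhance(enh, te$image)
      histories[[sprintf("enhancer_fold%d", f)]] <- enh$history
    }
    quant <- train_quantifier(tr$enhanced, normalize_count(tr$count, count_max),
                              config, seed = fold_seed + 1L)
    histories[[sprintf("quantifier_fold%d", f)]] <- quant$history
    pc <- predict_count(quant, te$enhanced, count_max)
    cnr <- purrr::map2_dbl(te$enhanced, te$mask,
                           function(im, m) part_cnr(im, m)$cnr)
    preds[[f]] <- tibble(
      subject_id = te$subject_id,
      slice_index = te$slice_index,
      hemisphere = te$hemisphere,
      fold = f,
      truth_count = te$count,
      pred_count = pc$count,
      truth_grade = te$grade,
      pred_grade = grade_from_count(pc$count),
      cnr = cnr
    )
  }
  pred <- dplyr::bind_rows(preds)
  sm <- summarize_predictions(pred)
  # ICC is undefined for < 5 subjects or zero-variance grades; report NA then
  safe_icc <- function(t, p) {
    tryCatch(icc(t, p), error = function(e) {
      tibble(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
             n = length(t), k = 2L, type = "agreement")
    })
  }
  icc_image <- safe_icc(pred$truth_grade, pred$pred_grade)
  icc_subject <- safe_icc(sm$subjects$truth_grade, sm$subjects$pred_grade)
  structure(list(
    method = method,
    predictions = pred,
    folds = folds,
    fold_subjects = fold_subjects,
    metrics = sm$pooled,
    per_fold = sm$per_fold,
    icc_image = icc_image,
    icc_subject = icc_subject,
    histories = histories,
    config = config,
    seed = seed,
    count_max = count_max
  ), class = "pvs_eval")
}

#' @exportS3Method generics::tidy
tidy.pvs_eval <- function(x, ...) x$per_fold

#' @exportS3Method generics::glance
glance.pvs_eval <- function(x, ...) {
  dplyr::bind_cols(
    tibble(method = x$method),
    dplyr::select(x$metrics, -"fold"),
    tibble(icc_image = x$icc_image$icc, icc_subject = x$icc_subject$icc)
  )
}

#' @export
print.pvs_eval <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<pvs_eval> method '%s', %d folds, %d pooled test images\n",
              x$method, attr(x$folds, "k"), nrow(x$predictions)))
  cat(sprintf("  MAE %.2f counts | image accuracy %.0f%% | subject accuracy %.0f%%\n",
              g$mae, g$image_accuracy, g$subject_accuracy))
  cat(sprintf("  ICC image %.3f, subject %.3f | mean CNR %s\n",
              g$icc_image, g$icc_subject,
              ifelse(is.na(g$mean_cnr), "NA", sprintf("%.1f", g$mean_cnr))))
  invisible(x)
}
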