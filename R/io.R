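#' Read and write portable graymap (PGM) images
#'
#' Part images and masks are stored as plain-text 16-bit PGM (P2), a portable
#' format readable by ImageJ/skimage/netpbm. (No NIfTI/TIFF writer is
#' available in this package's dependency footprint; the manifest CSV keeps
#' the cohort metadata either way.)
#'
#' @param mat Integer matrix of nonnegative values `<= maxval`.
#' @param path File path.
#' @param maxval Maximum gray value declared in the header.
#' @return `read_pgm()` returns an integer matrix; `write_pgm()` returns
#'   `path` invisibly.
#' @export
write_pgm <- function(mat, path, maxval = 65535L) {
  check_matrix(mat, "mat")
  if (min(mat) < 0 || max(mat) > maxval) stopf("values outside [0, maxval]")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(mat), nrow(mat)), as.character(maxval)), con)
  # raster order: one image row per line
  writeLines(apply(mat, 1, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path, class = "pvscade_missing_file")
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  if (txt[1] != "P2") stopf("%s: only ASCII PGM (P2) is supported", path)
  tokens <- scan(text = paste(txt[-1], collapse = "\n"), what = integer(),
                 quiet = TRUE)
  w <- tokens[1]; h <- tokens[2]
  vals <- tokens[-(1:3)]
  if (length(vals) != w * h) stopf("%s: corrupt PGM payload", path)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a phantom cohort to disk
#'
#' Writes per-part raw images and masks as 16-bit PGM under `dir/images` and
#' `dir/masks`, plus a `manifest.csv` with columns `subject_id`,
#' `slice_index`, `hemisphere`, `count`, `grade`, `image_path`, `mask_path`.
#'
#' @param cohort A `pvs_cohort` tibble from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param overwrite Refuse to write into an existing nonempty directory
#'   unless `TRUE`.
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir, overwrite = FALSE) {
  stopifnot(all(c("subject_id", "slice_index", "hemisphere", "count",
                  "grade", "raw", "mask") %in% names(cohort)))
  if (dir.exists(dir) && length(dir(dir)) > 0 && !overwrite) {
    stopf("output directory %s exists and is not empty (use overwrite)", dir)
  }
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  stem <- sprintf("%s_s%d_%s", cohort$subject_id, cohort$slice_index,
                  cohort$hemisphere)
  manifest <- tibble(
    subject_id = cohort$subject_id,
    slice_index = cohort$slice_index,
    hemisphere = cohort$hemisphere,
    count = cohort$count,
    grade = cohort$grade,
    image_path = file.path("images", paste0(stem, ".pgm")),
    mask_path = file.path("masks", paste0(stem, ".pgm"))
  )
  for (i in seq_len(nrow(cohort))) {
    write_pgm(cohort$raw[[i]], file.path(dir, manifest$image_path[i]))
    write_pgm(cohort$mask[[i]], file.path(dir, manifest$mask_path[i]), maxval = 1L)
  }
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort back from a manifest
#'
#' @param dir Directory containing `manifest.csv` as written by
#'   [write_cohort()] (or a direct path to a manifest CSV whose image paths
#'   are relative to its directory).
#' @return A `pvs_cohort`-shaped tibble with `raw` and `mask` list-columns.
#' @export
read_cohort <- function(dir) {
  manifest_path <- if (dir.exists(dir)) file.path(dir, "manifest.csv") else dir
  if (!file.exists(manifest_path)) {
    stopf("no manifest at %s", manifest_path, class = "pvscade_missing_file")
  }
  root <- dirname(manifest_path)
  m <- as_tibble(read.csv(manifest_path, stringsAsFactors = FALSE))
  cohort <- dplyr::mutate(m,
    raw = purrr::map(.data$image_path, ~ read_pgm(file.path(root, .x))),
    mask = purrr::map(.data$mask_path, ~ read_pgm(file.path(root, .x)))
  )
  cohort <- dplyr::group_by(cohort, .data$subject_id)
  cohort <- dplyr::ungroup(dplyr::mutate(cohort,
    subject_grade = as.integer(max(.data$grade))))
  structure(cohort, class = c("pvs_cohort", class(cohort)))
}

#' Serialize an evaluation report
#'
#' Writes `report.json` (method, config snapshot, seed, pooled and per-fold
#' metrics, ICCs) and `predictions.csv` (one row per test image) into `dir`.
#' Timestamps are kept out of the report so that seeded reruns are
#' byte-identical; the run manifest carries the timestamp instead.
#'
#' @param report A `pvs_eval` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pvs_eval"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  payload <- list(
    method = report$method,
    seed = report$seed,
    count_max = report$count_max,
    config = unclass(report$config),
    metrics = as.list(dplyr::select(report$metrics, -"fold")),
    per_fold = report$per_fold,
    icc_image = as.list(report$icc_image),
    icc_subject = as.list(report$icc_subject),
    folds = as.data.frame(report$folds)
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  write.csv(report$predictions, file.path(dir, "predictions.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Save and load fitted networks
#'
#' Checkpoints are RDS files accompanied by a small JSON sidecar declaring
#' the checkpoint schema version and architecture, so stale checkpoints fail
#' loudly instead of deserializing into the wrong shape.
#'
#' @param model A `pvs_enhancer` or `pvs_quantifier`.
#' @param path Checkpoint path (`.rds`; the sidecar gets `.json` appended).
#' @return `load_model()` returns the model; `save_model()` returns `path`
#'   invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, c("pvs_enhancer", "pvs_quantifier")))
  saveRDS(model, path)
  meta <- list(schema_version = 1L, kind = model$kind, arch = model$arch,
               package_version = as.character(utils::packageVersion("pvscade")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stopf("no such checkpoint: %s", path,
                                class = "pvscade_missing_file")
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (!identical(meta$schema_version, 1L) && !identical(meta$schema_version, 1)) {
      stopf("unsupported checkpoint schema version: %s", meta$schema_version)
    }
  }
  model <- readRDS(path)
  stopifnot(inherits(model, c("pvs_enhancer", "pvs_quantifier")))
  model
}
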