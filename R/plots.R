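# ggplot2 display methods

image_raster_df <- function(img, label) {
  tibble(
    row = rep(seq_len(nrow(img)), times = ncol(img)),
    col = rep(seq_len(ncol(img)), each = nrow(img)),
    value = as.numeric(img),
    part = label
  )
}

#' Plot a gallery of cohort parts
#'
#' @param object A `pvs_cohort` (plots `raw`) or `pvs_parts` tibble (plots
#'   the normalized `image`, or `enhanced` when present).
#' @param n Number of parts to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pvs_cohort <- function(object, n = 6, ...) {
  idx <- seq_len(min(n, nrow(object)))
  col <- if ("raw" %in% names(object)) "raw" else
    if ("enhanced" %in% names(object)) "enhanced" else "image"
  df <- purrr::map2(object[[col]][idx],
                    sprintf("%s s%d %s (n=%d)", object$subject_id[idx],
                            object$slice_index[idx], object$hemisphere[idx],
                            object$count[idx]),
                    image_raster_df) |>
    dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::facet_wrap(~part) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity")
}

#' @exportS3Method ggplot2::autoplot
autoplot.pvs_parts <- autoplot.pvs_cohort

#' Training-loss curve of a fitted network
#'
#' @param object A `pvs_enhancer` or `pvs_quantifier`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pvs_enhancer <- function(object, ...) {
  lab <- if (inherits(object, "pvs_enhancer")) "training MSE" else "training MAE"
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = lab)
}

#' @exportS3Method ggplot2::autoplot
autoplot.pvs_quantifier <- autoplot.pvs_enhancer

#' Predicted versus true ePVS counts of a cross-validation report
#'
#' @param object A `pvs_eval` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pvs_eval <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$truth_count, y = .data$pred_count,
                               colour = factor(.data$fold))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "true ePVS count", y = "predicted ePVS count",
                  colour = "fold",
                  title = sprintf("method '%s': MAE %.2f counts",
                                  object$method, object$metrics$mae))
}
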