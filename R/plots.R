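field_raster_df <- function(pixels) {
  tibble(
    row = rep(seq_len(nrow(pixels)), times = ncol(pixels)),
    col = rep(seq_len(ncol(pixels)), each = nrow(pixels)),
    value = as.numeric(pixels)
  )
}

#' Heatmap of an illumination correction function
#'
#' Visual review of the estimated functions is standard practice: debris,
#' blotches and asymmetric shading are immediately visible.
#'
#' @param object An `illum_icf`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.illum_icf <- function(object, ...) {
  df <- field_raster_df(object$pixels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "ICF") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("ICF %s / %s", object$group_value, object$channel),
      subtitle = sprintf("window %d px, %d images, variation %.1f%%",
                         object$window_px, object$n_images,
                         variation_percent(object)),
      x = NULL, y = NULL
    )
}

#' Heatmap of a mechanism-of-action confusion matrix
#'
#' @param object A `moa_confusion`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.moa_confusion <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$moa_predicted, y = .data$moa_true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_fill_viridis_c(name = "treatments") +
    ggplot2::labs(title = sprintf("MOA classification, accuracy %.1f%%", object$accuracy),
                  x = "predicted", y = "true")
}

#' Control-well readouts of an assay
#'
#' @param result An `assay_result`.
#' @return A ggplot object showing per-well readouts by control role.
#' @export
plot_well_readouts <- function(result) {
  df <- tidy(result)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$role, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(
      title = sprintf("Well readouts (%s): Z' = %.2f, one-tailed Z' = %.2f",
                      result$channel, result$zprime_two_tailed,
                      result$zprime_one_tailed),
      x = NULL, y = "median per-cell total intensity"
    )
}
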