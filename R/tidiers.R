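#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an assay result
#'
#' @param x An `assay_result` from [evaluate_assay()].
#' @param ... Unused.
#' @return The per-well readout tibble (`plate`, `well`, `role`, `value`,
#'   `n_cells`).
#' @export
tidy.assay_result <- function(x, ...) {
  x$well_readouts
}

#' One-row summary of an assay result
#'
#' @inheritParams tidy.assay_result
#' @return Tibble with `zprime_two_tailed`, `zprime_one_tailed`,
#'   `p_value_mean_difference`, `n_pos`, `n_neg`.
#' @export
glance.assay_result <- function(x, ...) {
  tibble(
    zprime_two_tailed = x$zprime_two_tailed,
    zprime_one_tailed = x$zprime_one_tailed,
    p_value_mean_difference = x$p_value_mean_difference,
    n_pos = x$n_pos,
    n_neg = x$n_neg
  )
}

#' Tidy a confusion matrix
#'
#' @param x A `moa_confusion` from [nn_classify_loco()].
#' @param ... Unused.
#' @return Long tibble with `moa_true`, `moa_predicted`, `n`.
#' @export
tidy.moa_confusion <- function(x, ...) {
  grid <- expand.grid(moa_true = x$labels, moa_predicted = x$labels,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid$n <- as.integer(x$counts[cbind(grid$moa_true, grid$moa_predicted)])
  as_tibble(grid)
}

#' One-row summary of a confusion matrix
#'
#' @inheritParams tidy.moa_confusion
#' @return Tibble with `accuracy` (percent), `n_treatments`, `n_classes`.
#' @export
glance.moa_confusion <- function(x, ...) {
  tibble(accuracy = x$accuracy,
         n_treatments = nrow(x$predictions),
         n_classes = length(x$labels))
}
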