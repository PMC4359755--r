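#' Per-well readout from per-cell totals
#'
#' The univariate screen readout: the median across all cells in a well of
#' the per-cell total channel intensity (midpoint interpolation for even
#' counts).
#'
#' @param cell_totals Numeric vector of per-cell totals, at least one cell.
#' @return The sample median.
#' @export
well_readout <- function(cell_totals) {
  if (length(cell_totals) == 0) stop_value("well_readout() requires at least one cell")
  median(cell_totals)
}

#' Z'-factor of a two-control assay
#'
#' `1 - 3 * (sd(pos) + sd(neg)) / |mean(pos) - mean(neg)|` with sample
#' (n-1) standard deviations; the standard separability measure for
#' screening assays.
#'
#' @param pos,neg Numeric vectors of positive/negative control readouts,
#'   at least 2 values each.
#' @return The Z'-factor (at most 1; can be arbitrarily negative).
#' @export
zprime <- function(pos, neg) {
  if (length(pos) < 2 || length(neg) < 2) {
    stop_value("zprime() needs at least 2 values per group")
  }
  delta <- abs(mean(pos) - mean(neg))
  if (delta == 0) stop_value("zprime() undefined: group means are equal")
  1 - 3 * (sd(pos) + sd(neg)) / delta
}

#' One-tailed Z'-factor
#'
#' Image-based readouts are typically asymmetric (per-cell intensities are
#' roughly lognormal), and the far tails then inflate the ordinary Z'.  The
#' one-tailed variant measures each control's spread only on the tail facing
#' the other control: with medians `m_pos` and `m_neg`, the facing tail of a
#' group is the set of its values lying between the two medians (inclusive),
#' and its one-sided spread is the root-mean-square deviation of that tail
#' from the group's own median.  The statistic is
#' `1 - 3 * (s_pos + s_neg) / |m_pos - m_neg|`.
#'
#' For distributions symmetric about their medians the facing-tail RMS is a
#' consistent estimator of the full standard deviation, so the one-tailed
#' value converges to [zprime()].
#'
#' @inheritParams zprime
#' @return The one-tailed Z'-factor.
#' @export
one_tailed_zprime <- function(pos, neg) {
  if (length(pos) < 2 || length(neg) < 2) {
    stop_value("one_tailed_zprime() needs at least 2 values per group")
  }
  m_pos <- median(pos)
  m_neg <- median(neg)
  if (m_pos == m_neg) stop_value("one_tailed_zprime() undefined: group medians are equal")
  lo <- min(m_pos, m_neg)
  hi <- max(m_pos, m_neg)
  tail_pos <- pos[pos >= lo & pos <= hi]
  tail_neg <- neg[neg >= lo & neg <= hi]
  if (length(tail_pos) == 0 || length(tail_neg) == 0) {
    stop_value("one_tailed_zprime() degenerate: a group has an empty facing tail")
  }
  s_pos <- sqrt(mean((tail_pos - m_pos)^2))
  s_neg <- sqrt(mean((tail_neg - m_neg)^2))
  1 - 3 * (s_pos + s_neg) / abs(m_pos - m_neg)
}

#' Welch test for a control mean difference
#'
#' Two-sided Welch (unequal variance) t-test between the control groups.
#' If both groups are constant with equal values the p-value is 1 by
#' convention.
#'
#' @inheritParams zprime
#' @return The two-sided p-value.
#' @export
mean_difference_test <- function(pos, neg) {
  if (length(pos) < 2 || length(neg) < 2) {
    stop_value("mean_difference_test() needs at least 2 values per group")
  }
  if (sd(pos) == 0 && sd(neg) == 0) {
    return(if (mean(pos) == mean(neg)) 1 else 0)
  }
  t.test(pos, neg, var.equal = FALSE)$p.value
}

#' Evaluate a univariate assay from a cell feature table
#'
#' Aggregates per-cell total intensity of the readout channel to one median
#' per control well ([well_readout()]), then scores the positive/negative
#' separation with the two-tailed and one-tailed Z'-factors and a Welch mean
#' difference test on the well-level values.
#'
#' @param cells Cell feature table (see [measure_image_set()]) with columns
#'   `plate`, `well`, `role` and `total_<channel>`.
#' @param channel Readout channel name (e.g. `"tubulin"`).
#' @param pos_role,neg_role Roles identifying the control wells.
#' @return An `assay_result` object; see [tidy.assay_result()] and
#'   [glance.assay_result()].
#' @export
evaluate_assay <- function(cells, channel,
                           pos_role = "positive_control",
                           neg_role = "negative_control") {
  col <- paste0("total_", channel)
  if (!col %in% names(cells)) {
    stop_config(paste0("cell table has no column ", col))
  }
  ctrl <- dplyr::filter(cells, .data$role %in% c(pos_role, neg_role))
  readouts <- ctrl |>
    dplyr::group_by(.data$plate, .data$well, .data$role) |>
    dplyr::summarise(value = well_readout(.data[[col]]),
                     n_cells = dplyr::n(), .groups = "drop")
  pos <- readouts$value[readouts$role == pos_role]
  neg <- readouts$value[readouts$role == neg_role]
  if (length(pos) < 2 || length(neg) < 2) {
    stop_value(sprintf("need >= 2 wells per control role, got %d positive / %d negative",
                       length(pos), length(neg)))
  }
  one_tailed <- tryCatch(
    one_tailed_zprime(pos, neg),
    illumfield_value_error = function(e) {
      warn(paste0("one-tailed Z' undefined for these controls (",
                  conditionMessage(e), "); reporting NA"))
      NA_real_
    }
  )
  structure(
    list(
      zprime_two_tailed = zprime(pos, neg),
      zprime_one_tailed = one_tailed,
      p_value_mean_difference = mean_difference_test(pos, neg),
      n_pos = length(pos),
      n_neg = length(neg),
      channel = channel,
      well_readouts = readouts
    ),
    class = "assay_result"
  )
}

#' @export
print.assay_result <- function(x, ...) {
  cat(sprintf("<assay_result> channel=%s  wells: %d positive / %d negative\n",
              x$channel, x$n_pos, x$n_neg))
  cat(sprintf("  Z' (two-tailed)  %.3f\n", x$zprime_two_tailed))
  cat(sprintf("  Z' (one-tailed)  %.3f\n", x$zprime_one_tailed))
  cat(sprintf("  Welch p (means)  %.3g\n", x$p_value_mean_difference))
  invisible(x)
}
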