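#' Percent intensity variation across a field
#'
#' The headline shading statistic: `100 * (1 - min/max)` of a positive field.
#' For an ICF this is the percentage by which the dimmest part of the field
#' of view falls below the brightest — the quantity that routinely reaches
#' 10--30% on plate-based acquisitions even after instrument white
#' referencing.
#'
#' @param field Positive numeric matrix (an ICF or a mean projection).
#' @return Percent in `[0, 100)`.
#' @export
variation_percent <- function(field) {
  px <- if (inherits(field, "illum_icf")) field$pixels else field
  if (any(px <= 0)) stop_data("variation_percent() requires a strictly positive field")
  100 * (1 - min(px) / max(px))
}

#' Residual-relief roughness of a smoothed field
#'
#' Quantifies "blotchiness": bright blotches in an ICF mean local cellular
#' intensities still dominate the global illumination pattern.  The score is
#' the 99th percentile of `|r - m| / m` where `r` is the field and `m` is the
#' same field re-smoothed with a small probe window (10% of the shorter
#' dimension by default).  A perfectly smooth field scores 0.
#'
#' @param smoothed Positive numeric matrix (typically a smoothed mean
#'   projection or an ICF).
#' @param probe_window Odd probe window; default `odd(0.1 * min(h, w))`.
#' @return Non-negative roughness score.
#' @export
roughness_metric <- function(smoothed, probe_window = NULL) {
  px <- if (inherits(smoothed, "illum_icf")) smoothed$pixels else smoothed
  if (any(px <= 0)) stop_data("roughness_metric() requires a strictly positive field")
  if (is.null(probe_window)) {
    probe_window <- min(odd_window(0.1 * min(dim(px))), odd_cap(min(dim(px))))
  }
  m <- median_smooth(px, probe_window)
  unname(quantile(abs(px - m) / m, 0.99))
}

#' Cell-density uniformity map
#'
#' Checks the assumption behind batch-wise ICF estimation that cells are
#' uniformly distributed across the field of view: segments each image of a
#' channel (Otsu threshold on a lightly Gaussian-smoothed copy), averages the
#' binary masks across images, median-smooths the average, and summarizes
#' departure from uniformity as [variation_percent()] of the smoothed map
#' offset by +1 (the offset guarantees a positive domain for the ratio
#' metric; blank images give an all-zero map and 0%).
#'
#' @param images Image-set tibble.
#' @param channel Channel to assess (typically the nuclear stain).
#' @param sigma Gaussian pre-smoothing sigma in pixels.
#' @param threshold Uniformity threshold in percent used for the `uniform`
#'   verdict.
#' @return List with `map` (raw mean mask), `smoothed`, `uniformity_percent`,
#'   `uniform` (logical verdict), and `n_images`.
#' @export
cell_density_map <- function(images, channel, sigma = 2, threshold = 20) {
  records <- images[images$channel == channel, ]
  if (nrow(records) == 0) stop_value(paste0("no images for channel ", channel))
  if (nrow(records) < 10) {
    warn(sprintf("cell_density_map(): only %d image(s) in channel %s; map will be noisy",
                 nrow(records), channel))
  }
  acc <- NULL
  for (i in seq_len(nrow(records))) {
    img <- load_image(records[i, ])
    mask <- segment_foreground(img, sigma = sigma)
    acc <- if (is.null(acc)) mask else acc + mask
  }
  map <- acc / nrow(records)
  probe <- min(odd_window(0.1 * min(dim(map))), odd_cap(min(dim(map))))
  smoothed <- median_smooth(map, probe)
  uniformity <- variation_percent(smoothed + 1)
  list(map = map, smoothed = smoothed, uniformity_percent = uniformity,
       uniform = uniformity <= threshold, n_images = nrow(records))
}

# Otsu foreground mask on a lightly smoothed copy; all-background images
# (near-zero dynamic range) return an all-FALSE mask.  The threshold is
# computed with the histogram clipped at the 99.5th percentile so that one
# extremely bright object cannot drag the threshold above the other cells.
segment_foreground <- function(image, sigma = 2) {
  top <- max(image)
  if (top <= 0 || diff(range(image)) < .Machine$double.eps * top) {
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  sm <- gaussian_smooth(image, sigma)
  cap <- quantile(sm, 0.995)
  if (cap <= min(sm)) cap <- max(sm)
  clipped <- pmin(sm, cap)
  thr <- EBImage::otsu(EBImage::Image(clipped / cap), range = c(0, 1)) * cap
  sm > thr
}

gaussian_smooth <- function(image, sigma) {
  as.matrix(EBImage::imageData(EBImage::gblur(EBImage::Image(image), sigma = sigma)))
}

#' Cross-group ICF outlier detection
#'
#' A single unusual ICF among the plates of an experiment often traces back
#' to a single image with intense debris.  Each ICF is scored as
#' `1 - median(Pearson correlation with every other ICF)`; an ICF is flagged
#' when its score exceeds `median(scores) + 3 * MAD(scores)` or the absolute
#' backstop 0.2.
#'
#' @param icfs List of at least 3 `illum_icf` objects of one channel and
#'   shape.
#' @return Tibble with `group_value`, `channel`, `score`, `flag`, in input
#'   order.
#' @export
icf_outlier_scores <- function(icfs) {
  if (length(icfs) < 3) stop_value("icf_outlier_scores() needs at least 3 ICFs")
  chans <- vapply(icfs, function(i) i$channel, character(1))
  if (length(unique(chans)) != 1) stop_data("ICFs mix channels")
  shapes <- vapply(icfs, function(i) paste(dim(i$pixels), collapse = "x"), character(1))
  if (length(unique(shapes)) != 1) stop_data("ICFs have differing shapes")
  vecs <- vapply(icfs, function(i) as.numeric(i$pixels), numeric(length(icfs[[1]]$pixels)))
  cm <- suppressWarnings(cor(vecs))
  cm[is.na(cm)] <- 1  # constant fields correlate perfectly with themselves in spirit
  scores <- vapply(seq_along(icfs), function(i) 1 - median(cm[i, -i]), numeric(1))
  fence <- median(scores) + 3 * mad(scores)
  tibble(
    group_value = vapply(icfs, function(i) i$group_value, character(1)),
    channel = chans,
    score = scores,
    flag = scores > fence | scores > 0.2
  )
}

#' Quality-control report for a set of ICFs
#'
#' Per-ICF percent variation and roughness, plus cross-ICF outlier scores
#' (computed per channel when at least 3 ICFs of a channel are present).
#'
#' @param icfs Named list of `illum_icf` objects.
#' @return Tibble with one row per ICF: `group_value`, `channel`,
#'   `variation_percent`, `roughness`, `outlier_score`, `outlier_flag`.
#' @export
qc_report <- function(icfs) {
  base <- purrr::map_dfr(icfs, function(icf) {
    tibble(group_value = icf$group_value, channel = icf$channel,
           variation_percent = variation_percent(icf),
           roughness = roughness_metric(icf))
  })
  base$outlier_score <- NA_real_
  base$outlier_flag <- NA
  for (ch in unique(base$channel)) {
    idx <- which(base$channel == ch)
    if (length(idx) >= 3) {
      sc <- icf_outlier_scores(icfs[idx])
      base$outlier_score[idx] <- sc$score
      base$outlier_flag[idx] <- sc$flag
    }
  }
  base
}
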