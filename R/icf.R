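#' Construct an illumination correction function object
#'
#' An ICF is a smooth, strictly positive 2D field estimated per (group,
#' channel); images are corrected by dividing by it.  After rescaling its
#' minimum is 1, so correction only attenuates pixels.
#'
#' @param pixels Positive numeric matrix with `min(pixels) == 1` (tolerance
#'   `1e-6`).
#' @param channel Channel identifier.
#' @param group_key Grouping key, one of `"plate"`, `"row"`, `"column"`,
#'   `"site"`.
#' @param group_value Identifier of the group the ICF was estimated from.
#' @param window_px Odd median-filter window used for smoothing.
#' @param n_images Number of images averaged.
#' @param created_utc Creation timestamp (UTC, ISO 8601).
#' @return An object of class `illum_icf`.
#' @export
new_icf <- function(pixels, channel, group_key = "plate", group_value = NA_character_,
                    window_px = NA_integer_, n_images = NA_integer_,
                    created_utc = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")) {
  icf <- structure(
    list(pixels = pixels, channel = channel, group_key = group_key,
         group_value = group_value, window_px = as.integer(window_px),
         n_images = as.integer(n_images), created_utc = created_utc),
    class = "illum_icf"
  )
  validate_icf(icf)
  icf
}

validate_icf <- function(icf) {
  if (!inherits(icf, "illum_icf")) stop_value("not an illum_icf object")
  px <- icf$pixels
  if (!is.matrix(px) || !is.numeric(px)) stop_value("ICF pixels must be a numeric matrix")
  if (anyNA(px) || any(!is.finite(px))) stop_data("ICF contains non-finite pixels")
  if (any(px <= 0)) stop_data("ICF contains non-positive pixels")
  if (abs(min(px) - 1) > 1e-6) {
    stop_value(sprintf("ICF is not rescaled to min 1 (min = %.8g)", min(px)))
  }
  if (!is.na(icf$window_px)) {
    w <- icf$window_px
    if (w %% 2 == 0 || w < 1 || w > min(dim(px))) {
      stop_value("ICF window_px must be odd and within image dimensions")
    }
  }
  invisible(icf)
}

#' @export
print.illum_icf <- function(x, ...) {
  cat(sprintf("<illum_icf> %dx%d  channel=%s  %s=%s  window=%d px  n_images=%d\n",
              nrow(x$pixels), ncol(x$pixels), x$channel, x$group_key,
              x$group_value, x$window_px, x$n_images))
  cat(sprintf("  range [%.4f, %.4f]  variation %.1f%%\n",
              min(x$pixels), max(x$pixels), variation_percent(x$pixels)))
  invisible(x)
}

#' Pixelwise mean projection of an image batch
#'
#' The first step of ICF estimation: averaging all images of a channel in an
#' experimental batch.  Accumulation is in double precision, so 16-bit input
#' cannot overflow.
#'
#' @param images List of numeric matrices of identical shape.
#' @return Numeric matrix, the pixelwise arithmetic mean.
#' @export
mean_projection <- function(images) {
  if (length(images) == 0) stop_value("mean_projection() needs at least one image")
  shape <- dim(images[[1]])
  acc <- matrix(0, shape[1], shape[2])
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (!identical(dim(img), shape)) {
      stop_data(sprintf("image %d has shape %dx%d, expected %dx%d",
                        i, nrow(img), ncol(img), shape[1], shape[2]))
    }
    acc <- acc + img
  }
  acc / length(images)
}

median_projection <- function(images) {
  if (length(images) == 0) stop_value("median_projection() needs at least one image")
  shape <- dim(images[[1]])
  stack <- vapply(images, function(img) {
    if (!identical(dim(img), shape)) stop_data("image shape mismatch in projection")
    as.numeric(img)
  }, numeric(prod(shape)))
  matrix(apply(stack, 1, median), shape[1], shape[2])
}

#' Median-filter smoothing
#'
#' Replaces each pixel by the exact median of its `window_px` x `window_px`
#' square neighbourhood; borders are handled by reflect padding (mirrored
#' without repeating the edge pixel), which avoids the dark-border bias of
#' zero padding at the large windows (~40% of the image) this pipeline uses.
#'
#' @param image Numeric matrix.
#' @param window_px Odd window side length, between 1 and `min(dim(image))`.
#' @return Smoothed matrix of the same shape.
#' @export
median_smooth <- function(image, window_px) {
  if (!is.matrix(image) || !is.numeric(image)) stop_value("image must be a numeric matrix")
  window_px <- as.integer(window_px)
  if (is.na(window_px) || window_px < 1 || window_px %% 2 == 0) {
    stop_value("window_px must be a positive odd integer")
  }
  if (window_px > min(dim(image))) {
    stop_value(sprintf("window_px (%d) exceeds the shorter image dimension (%d)",
                       window_px, min(dim(image))))
  }
  median_filter_reflect(image, window_px)
}

#' Rescale a smoothed field to minimum 1
#'
#' Divides by the field minimum so that correction by division only ever
#' attenuates intensities.  A non-positive pixel signals over-aggressive
#' smoothing of empty images or dark-frame input and is rejected.
#'
#' @param smoothed Positive numeric matrix.
#' @return Matrix with minimum exactly 1.
#' @export
rescale_icf <- function(smoothed) {
  if (any(smoothed <= 0)) {
    stop_data("smoothed field contains non-positive pixels; cannot rescale")
  }
  smoothed / min(smoothed)
}

# smallest odd integer >= floor(x); the convention used for all derived
# window sizes (odd(256) = 257, odd(102.4) = 103)
odd_window <- function(x) {
  2L * as.integer(floor(x / 2)) + 1L
}

# largest valid odd window for a given shorter dimension
odd_cap <- function(s) {
  s <- as.integer(s)
  if (s %% 2L == 1L) s else s - 1L
}

#' Default median window for a given image shape
#'
#' For the canonical 1280 x 1024 acquisition the default is 501 px (the
#' published 500 px window, standardized to odd); otherwise 40% of the
#' shorter dimension, rounded up to odd, since 500/1280 is about 0.39.
#'
#' @param shape Integer vector `c(height, width)`.
#' @return Odd integer window size.
#' @export
default_window_px <- function(shape) {
  s <- sort(as.integer(shape))
  if (identical(s, c(1024L, 1280L))) return(501L)
  min(odd_window(0.4 * s[1]), odd_cap(s[1]))
}

# composite group value for each record under a grouping key; grouping never
# mixes plates or channels
group_value_of <- function(records, key) {
  switch(key,
    plate = records$plate,
    row = paste0(records$plate, ":row=", records$well_row),
    column = paste0(records$plate, ":col=", records$well_col),
    site = paste0(records$plate, ":site=", records$site),
    stop_value(paste0("unknown grouping key: ", key))
  )
}

grouping_keys <- c("plate", "row", "column", "site")

#' Estimate an illumination correction function
#'
#' The core estimator: mean projection over all images matching the given
#' group and channel, median-filter smoothing, and rescaling to minimum 1.
#'
#' @param images Image-set tibble (see [read_image_set()]).
#' @param channel Channel to estimate for.
#' @param group_value Group identifier; for `grouping = "plate"` simply the
#'   plate name, otherwise the composite `"<plate>:row=<r>"` style value (see
#'   [estimate_icfs()] which enumerates them).
#' @param grouping Grouping key: `"plate"` (the usual experimental batch),
#'   `"row"`, `"column"` or `"site"`.
#' @param window_px Odd median window in pixels, `NULL` for the shape-derived
#'   default ([default_window_px()]), or `"auto"` to run
#'   [select_window_size()] on the mean projection.
#' @param projection `"mean"` (default, the standard estimator) or
#'   `"median"` (robust to rare debris-laden images).
#' @return An `illum_icf` object.
#' @export
estimate_icf <- function(images, channel, group_value = NULL,
                         grouping = "plate", window_px = NULL,
                         projection = c("mean", "median")) {
  projection <- match.arg(projection)
  grouping <- match.arg(grouping, grouping_keys)
  gv <- group_value_of(images, grouping)
  if (is.null(group_value)) {
    group_value <- unique(gv[images$channel == channel])
    if (length(group_value) != 1) {
      stop_value("group_value must be given when the set spans several groups")
    }
  }
  sel <- images$channel == channel & gv == group_value
  if (!any(sel)) {
    stop_value(sprintf("no images for channel '%s' in group '%s'", channel, group_value))
  }
  records <- images[sel, ]
  if (nrow(records) == 1) {
    warn(sprintf("group '%s'/%s has a single image; its ICF will reflect that image's content",
                 group_value, channel))
  }
  pixels <- lapply(seq_len(nrow(records)), function(i) load_image(records[i, ]))
  proj <- if (projection == "mean") mean_projection(pixels) else median_projection(pixels)
  if (identical(window_px, "auto")) {
    window_px <- select_window_size(proj)
  } else if (is.null(window_px)) {
    window_px <- default_window_px(dim(proj))
  }
  smoothed <- median_smooth(proj, window_px)
  new_icf(rescale_icf(smoothed),
          channel = channel, group_key = grouping, group_value = group_value,
          window_px = as.integer(window_px), n_images = nrow(records))
}

#' Estimate ICFs for every (group, channel) in an image set
#'
#' @inheritParams estimate_icf
#' @return Named list of `illum_icf` objects, keyed `"<group_value>/<channel>"`.
#' @export
estimate_icfs <- function(images, grouping = "plate", window_px = NULL,
                          projection = c("mean", "median")) {
  projection <- match.arg(projection)
  grouping <- match.arg(grouping, grouping_keys)
  gv <- group_value_of(images, grouping)
  combos <- dplyr::distinct(tibble(group_value = gv, channel = images$channel))
  icfs <- purrr::pmap(combos, function(group_value, channel) {
    estimate_icf(images, channel = channel, group_value = group_value,
                 grouping = grouping, window_px = window_px,
                 projection = projection)
  })
  names(icfs) <- paste0(combos$group_value, "/", combos$channel)
  icfs
}

icf_key <- function(group_value, channel) paste0(group_value, "/", channel)

#' Select a median window by the published heuristic
#'
#' Starts at approximately 25% of the shorter image dimension and grows in
#' increments of about 10% of it until the smoothed mean projection is smooth
#' overall, i.e. its residual-relief roughness ([roughness_metric()]) falls
#' below `roughness_tol`.  Capped at the image size; if the cap is reached
#' without meeting the tolerance the cap is returned with attribute
#' `converged = FALSE` (a flag, not an error).
#'
#' @param mean_image Mean projection to probe.
#' @param step_fraction Increment as a fraction of the shorter dimension.
#' @param start_fraction Starting window as a fraction of the shorter
#'   dimension.
#' @param roughness_tol Roughness threshold declaring the result smooth.
#'   The default 0.005 demands residual relief below about half a percent of
#'   the local field — an order of magnitude under the 10--30% anomalies
#'   being estimated.
#' @return Odd integer window with attributes `converged` (logical) and
#'   `roughness` (the achieved score).
#' @export
select_window_size <- function(mean_image, step_fraction = 0.10,
                               start_fraction = 0.25, roughness_tol = 0.005) {
  if (start_fraction <= 0 || start_fraction >= 1) stop_value("start_fraction must be in (0, 1)")
  if (step_fraction <= 0 || step_fraction >= 1) stop_value("step_fraction must be in (0, 1)")
  s <- min(dim(mean_image))
  cap <- odd_cap(s)
  candidates <- window_candidates(s, step_fraction, start_fraction)
  rough <- NA_real_
  for (w in candidates) {
    rough <- roughness_metric(median_smooth(mean_image, w))
    if (rough <= roughness_tol) {
      return(structure(w, converged = TRUE, roughness = rough))
    }
  }
  structure(cap, converged = FALSE, roughness = rough)
}

# the heuristic's candidate ladder: odd(start*s), then +step*s steps, capped
window_candidates <- function(s, step_fraction = 0.10, start_fraction = 0.25) {
  cap <- odd_cap(s)
  w <- min(odd_window(start_fraction * s), cap)
  out <- w
  while (w < cap) {
    w <- min(odd_window(w + step_fraction * s), cap)
    if (w <= out[length(out)]) w <- min(out[length(out)] + 2L, cap)
    out <- c(out, w)
  }
  unique(out)
}
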