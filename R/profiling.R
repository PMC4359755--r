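#' Segment cells in a nuclear image
#'
#' Minimal segmentation sufficient to measure the effect of illumination
#' correction on downstream profiling: Otsu threshold on a Gaussian-smoothed
#' copy (sigma 2 px), 8-connected component labelling, and removal of
#' components below a minimum area.  Blank images yield zero labels.
#'
#' @param nuclear_image Numeric matrix (nuclear channel).
#' @param min_area_px Minimum component area kept.
#' @param sigma Gaussian pre-smoothing sigma.
#' @return Integer label matrix: background 0, cells 1..n.
#' @export
segment_cells <- function(nuclear_image, min_area_px = 20, sigma = 2) {
  mask <- segment_foreground(nuclear_image, sigma = sigma)
  if (!any(mask)) return(matrix(0L, nrow(nuclear_image), ncol(nuclear_image)))
  labels <- label_components8(mask)
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes >= min_area_px)
  if (length(keep) == 0) return(matrix(0L, nrow(nuclear_image), ncol(nuclear_image)))
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(labels), ncol(labels))
  nz <- labels > 0
  out[nz] <- remap[labels[nz]]
  out
}

#' Measure per-cell features over one or more channels
#'
#' For each labelled cell: area, intensity-independent centroid, and per
#' channel the total and mean intensity over the cell's pixels.
#'
#' @param labels Integer label matrix from [segment_cells()].
#' @param channel_images Named list of numeric matrices, one per channel,
#'   sharing the mask's shape.
#' @return Tibble with one row per cell: `cell_id`, `area_px`,
#'   `centroid_row`, `centroid_col`, then `total_<ch>` and `mean_<ch>` per
#'   channel.  Empty mask gives an empty tibble.
#' @export
measure_cells <- function(labels, channel_images) {
  for (ch in names(channel_images)) {
    if (!identical(dim(channel_images[[ch]]), dim(labels))) {
      stop_data(paste0("channel image '", ch, "' shape does not match the label mask"))
    }
  }
  ids <- sort(unique(labels[labels > 0]))
  cols <- c(list(cell_id = integer(0), area_px = integer(0),
                 centroid_row = numeric(0), centroid_col = numeric(0)),
            setNames(rep(list(numeric(0)), 2 * length(channel_images)),
                     c(paste0("total_", names(channel_images)),
                       paste0("mean_", names(channel_images)))))
  if (length(ids) == 0) return(as_tibble(cols))
  lab_vec <- as.integer(labels)
  nz <- which(lab_vec > 0)
  f <- factor(lab_vec[nz], levels = ids)
  area <- as.integer(table(f))
  rows <- ((nz - 1) %% nrow(labels))
  colsix <- ((nz - 1) %/% nrow(labels))
  out <- tibble(
    cell_id = ids,
    area_px = area,
    centroid_row = as.numeric(tapply(rows, f, mean)),
    centroid_col = as.numeric(tapply(colsix, f, mean))
  )
  for (ch in names(channel_images)) {
    tot <- as.numeric(tapply(channel_images[[ch]][nz], f, sum))
    out[[paste0("total_", ch)]] <- tot
    out[[paste0("mean_", ch)]] <- tot / area
  }
  out
}

#' Segment and measure every site of an image set
#'
#' Runs [segment_cells()] on the nuclear channel of each (plate, well, site)
#' and [measure_cells()] across all channels acquired at that site, then
#' tags each cell with its well metadata (compound, concentration, role,
#' MOA).
#'
#' @param images Image-set tibble.
#' @param nuclear_channel Channel used for segmentation.
#' @param min_area_px,sigma Passed to [segment_cells()].
#' @return Cell feature table: one row per cell with identifiers, features
#'   and treatment annotation.
#' @export
measure_image_set <- function(images, nuclear_channel, min_area_px = 20, sigma = 2) {
  if (!nuclear_channel %in% images$channel) {
    stop_config(paste0("nuclear channel '", nuclear_channel, "' not present in the image set"))
  }
  sites <- dplyr::distinct(images[, c("plate", "well_row", "well_col", "well", "site")])
  res <- purrr::pmap(sites, function(plate, well_row, well_col, well, site) {
    recs <- images[images$plate == plate & images$well == well & images$site == site, ]
    imgs <- setNames(
      lapply(seq_len(nrow(recs)), function(i) load_image(recs[i, ])),
      recs$channel
    )
    if (!nuclear_channel %in% names(imgs)) return(NULL)
    labels <- segment_cells(imgs[[nuclear_channel]], min_area_px = min_area_px, sigma = sigma)
    cells <- measure_cells(labels, imgs)
    if (nrow(cells) == 0) return(NULL)
    meta <- recs[recs$channel == nuclear_channel, ][1, ]
    dplyr::bind_cols(
      tibble(plate = plate, well = well, site = site,
             compound = meta$compound, concentration = meta$concentration,
             role = meta$role, moa = meta$moa)[rep(1, nrow(cells)), ],
      cells
    )
  })
  dplyr::bind_rows(res)
}

feature_columns <- function(cells) {
  grep("^(area_px$|total_|mean_)", names(cells), value = TRUE)
}

#' Normalize cell features against plate controls
#'
#' Z-scores every cell's features against the mean and standard deviation of
#' the same plate's control cells — the reference-distribution normalization
#' that removes plate-to-plate intensity scale before profiles are pooled.
#' Features whose control s.d. is zero on any plate are dropped study-wide
#' with a warning.
#'
#' @param cells Cell feature table.
#' @param control_role Role defining the reference cells.
#' @param min_control_cells Warn when a plate has fewer control cells.
#' @return The cell table with feature columns replaced by their per-plate
#'   z-scores; dropped features recorded in attribute `"dropped_features"`.
#' @export
normalize_features <- function(cells, control_role = "negative_control",
                               min_control_cells = 100) {
  feats <- feature_columns(cells)
  if (length(feats) == 0) stop_config("no feature columns (area_px, total_*, mean_*) found")
  plates <- unique(cells$plate)
  stats_by_plate <- list()
  dropped <- character(0)
  for (p in plates) {
    ctrl <- cells[cells$plate == p & cells$role == control_role, feats, drop = FALSE]
    if (nrow(ctrl) == 0) {
      stop_value(paste0("plate ", p, " has no control cells of role ", control_role))
    }
    if (nrow(ctrl) < 20) {
      warn(sprintf("plate %s has only %d control cells; normalization will be unstable", p, nrow(ctrl)))
    } else if (nrow(ctrl) < min_control_cells) {
      warn(sprintf("plate %s has %d control cells (< %d recommended)", p, nrow(ctrl), min_control_cells))
    }
    mu <- vapply(ctrl, mean, numeric(1))
    sigma <- vapply(ctrl, sd, numeric(1))
    dropped <- union(dropped, feats[sigma == 0])
    stats_by_plate[[p]] <- list(mu = mu, sigma = sigma)
  }
  if (length(dropped) > 0) {
    warn(paste0("dropping constant-in-controls feature(s) study-wide: ",
                paste(dropped, collapse = ", ")))
  }
  keep <- setdiff(feats, dropped)
  out <- cells
  for (p in plates) {
    idx <- which(out$plate == p)
    st <- stats_by_plate[[p]]
    for (f in keep) {
      out[[f]][idx] <- (out[[f]][idx] - st$mu[[f]]) / st$sigma[[f]]
    }
  }
  out <- out[, setdiff(names(out), dropped)]
  attr(out, "dropped_features") <- dropped
  out
}

treatment_id <- function(compound, concentration) {
  sprintf("%s@%g", compound, concentration)
}

#' Mean per-treatment profiles
#'
#' One profile per (compound, concentration): the per-feature mean over all
#' of the treatment's cells, pooled across wells, sites and plates (after
#' per-plate normalization).
#'
#' @param cells Normalized cell feature table.
#' @return Tibble with `compound`, `concentration`, `moa`, `n_cells`, then
#'   one column per feature.
#' @export
treatment_profiles <- function(cells) {
  feats <- feature_columns(cells)
  cells |>
    dplyr::group_by(.data$compound, .data$concentration) |>
    dplyr::summarise(
      moa = .data$moa[1],
      n_cells = dplyr::n(),
      dplyr::across(dplyr::all_of(feats), mean),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$compound, .data$concentration)
}

cosine_distance <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(1)
  1 - sum(a * b) / (na * nb)
}

#' Leave-one-compound-out nearest-neighbour MOA classification
#'
#' Predicts each treatment profile's mechanism of action as the MOA of its
#' nearest neighbour among the profiles of *other* compounds (all profiles
#' of the query's own compound are excluded, preventing same-compound
#' leakage).  Ties are broken by lexicographic treatment identifier, making
#' the classification deterministic.
#'
#' @param profiles Profile tibble from [treatment_profiles()]; every profile
#'   must carry a known MOA and at least 2 compounds must be present.
#' @param metric `"cosine"` (default) or `"euclidean"`.
#' @return A `moa_confusion` object: confusion matrix (rows = true MOA,
#'   columns = predicted), overall percent accuracy, and the per-profile
#'   predictions.
#' @export
nn_classify_loco <- function(profiles, metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  if (any(is.na(profiles$moa) | profiles$moa == "unknown")) {
    stop_value("every profile must have a known MOA (drop unknowns before classifying)")
  }
  if (length(unique(profiles$compound)) < 2) {
    stop_value("nn_classify_loco() needs profiles from at least 2 compounds")
  }
  feats <- feature_columns(profiles)
  x <- as.matrix(profiles[, feats, drop = FALSE])
  n <- nrow(x)
  tid <- treatment_id(profiles$compound, profiles$concentration)
  pred <- character(n)
  nn_tid <- character(n)
  nn_dist <- numeric(n)
  for (i in seq_len(n)) {
    cand <- which(profiles$compound != profiles$compound[i])
    if (length(cand) == 0) {
      stop_value(paste0("profile ", tid[i], " has no candidates from other compounds"))
    }
    d <- vapply(cand, function(j) {
      if (metric == "cosine") cosine_distance(x[i, ], x[j, ])
      else sqrt(sum((x[i, ] - x[j, ])^2))
    }, numeric(1))
    ord <- order(d, tid[cand])
    best <- cand[ord[1]]
    pred[i] <- profiles$moa[best]
    nn_tid[i] <- tid[best]
    nn_dist[i] <- d[ord[1]]
  }
  labels <- sort(unique(c(profiles$moa, pred)))
  counts <- table(factor(profiles$moa, levels = labels),
                  factor(pred, levels = labels))
  counts <- matrix(as.integer(counts), length(labels), length(labels),
                   dimnames = list(true = labels, predicted = labels))
  structure(
    list(
      labels = labels,
      counts = counts,
      accuracy = 100 * sum(diag(counts)) / n,
      predictions = tibble(
        compound = profiles$compound,
        concentration = profiles$concentration,
        moa_true = profiles$moa,
        moa_predicted = pred,
        neighbour = nn_tid,
        distance = nn_dist
      )
    ),
    class = "moa_confusion"
  )
}

#' @export
print.moa_confusion <- function(x, ...) {
  cat(sprintf("<moa_confusion> %d treatments, %d MOA classes, accuracy %.1f%%\n",
              nrow(x$predictions), length(x$labels), x$accuracy))
  print(x$counts)
  invisible(x)
}

profile_chain <- function(images, nuclear_channel, control_role, metric,
                          min_area_px, sigma) {
  cells <- measure_image_set(images, nuclear_channel,
                             min_area_px = min_area_px, sigma = sigma)
  norm <- normalize_features(cells, control_role = control_role)
  usable <- dplyr::filter(norm, .data$role == "sample",
                          !is.na(.data$moa), .data$moa != "unknown")
  nn_classify_loco(treatment_profiles(usable), metric = metric)
}

#' Effect of illumination correction on MOA classification
#'
#' Runs the identical profiling chain (segment, measure, normalize against
#' plate controls, average into treatment profiles, leave-one-compound-out
#' nearest-neighbour classification) on an uncorrected and a corrected
#' version of the same study and reports both accuracies.
#'
#' @param uncorrected,corrected Image-set tibbles sharing metadata (same
#'   plates, wells, sites, channels and treatments).
#' @param nuclear_channel Segmentation channel.
#' @param control_role Reference role for normalization.
#' @param metric Profile distance metric.
#' @param min_area_px,sigma Segmentation parameters.
#' @return List with `accuracy_uncorrected`, `accuracy_corrected` (percent)
#'   and the two `moa_confusion` objects.
#' @export
compare_correction_effect <- function(uncorrected, corrected,
                                      nuclear_channel,
                                      control_role = "negative_control",
                                      metric = "cosine",
                                      min_area_px = 20, sigma = 2) {
  key_u <- uncorrected[order(uncorrected$plate, uncorrected$well, uncorrected$site, uncorrected$channel),
                       c(image_key_cols, "compound", "concentration", "role", "moa")]
  key_c <- corrected[order(corrected$plate, corrected$well, corrected$site, corrected$channel),
                     c(image_key_cols, "compound", "concentration", "role", "moa")]
  if (!isTRUE(all.equal(as.data.frame(key_u), as.data.frame(key_c),
                        check.attributes = FALSE))) {
    stop_data("uncorrected and corrected image sets have mismatched metadata")
  }
  conf_u <- profile_chain(uncorrected, nuclear_channel, control_role, metric,
                          min_area_px, sigma)
  conf_c <- profile_chain(corrected, nuclear_channel, control_role, metric,
                          min_area_px, sigma)
  list(
    accuracy_uncorrected = conf_u$accuracy,
    accuracy_corrected = conf_c$accuracy,
    confusion_uncorrected = conf_u,
    confusion_corrected = conf_c
  )
}
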