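#' Parametric shading-field description
#'
#' Describes a smooth multiplicative illumination field.  `amplitude` is the
#' peak-to-trough fractional drop, targeting the 10--30% regime typical of
#' plate-based acquisitions; the generated field always has maximum exactly
#' 1 and minimum exactly `1 - amplitude`.
#'
#' @param kind `"gaussian_vignette"` (bright centre, dark corners),
#'   `"planar_gradient"` (linear ramp) or `"off_axis_blob"` (Gaussian hot
#'   spot away from centre).
#' @param amplitude Fractional drop in `[0, 0.5]`.
#' @param centre `(row_frac, col_frac)` in `[0, 1]^2`: the Gaussian centre,
#'   or for `planar_gradient` the direction the ramp increases towards.
#' @param width_frac Gaussian width as a fraction of the shorter dimension.
#' @return A `field_params` object.
#' @export
field_params <- function(kind = c("gaussian_vignette", "planar_gradient", "off_axis_blob"),
                         amplitude = 0.25, centre = NULL, width_frac = NULL) {
  kind <- match.arg(kind)
  if (amplitude < 0 || amplitude > 0.5) {
    stop_value("field amplitude must be in [0, 0.5]")
  }
  centre <- centre %||% switch(kind,
    gaussian_vignette = c(0.5, 0.5),
    planar_gradient = c(0.2, 0.8),
    off_axis_blob = c(0.3, 0.7)
  )
  width_frac <- width_frac %||% switch(kind,
    gaussian_vignette = 0.25, planar_gradient = 0.5, off_axis_blob = 0.25
  )
  if (any(centre < 0) || any(centre > 1)) stop_value("centre fractions must be in [0, 1]")
  if (width_frac <= 0) stop_value("width_frac must be positive")
  structure(list(kind = kind, amplitude = amplitude, centre = centre,
                 width_frac = width_frac), class = "field_params")
}

#' Generate a shading field
#'
#' Deterministically builds the smooth positive multiplicative field
#' described by `params`, rescaled so that `max == 1` and
#' `min == 1 - amplitude` exactly.
#'
#' @param shape `c(height, width)`.
#' @param params A [field_params()] object.
#' @return Numeric matrix, the field.
#' @export
make_illumination_field <- function(shape, params) {
  h <- shape[1]
  w <- shape[2]
  if (params$amplitude == 0) return(matrix(1, h, w))
  cr <- params$centre[1] * (h - 1) + 1
  cc <- params$centre[2] * (w - 1) + 1
  g <- switch(params$kind,
    gaussian_vignette = ,
    off_axis_blob = {
      sig <- params$width_frac * min(h, w)
      d2 <- outer((seq_len(h) - cr)^2, (seq_len(w) - cc)^2, "+")
      exp(-d2 / (2 * sig^2))
    },
    planar_gradient = {
      dir <- params$centre - c(0.5, 0.5)
      if (all(dir == 0)) dir <- c(1, 1)
      dir <- dir / sqrt(sum(dir^2))
      outer(seq_len(h) / h * dir[1], seq_len(w) / w * dir[2], "+")
    }
  )
  ghat <- (g - min(g)) / (max(g) - min(g))
  (1 - params$amplitude) + params$amplitude * ghat
}

#' Simulation configuration
#'
#' Defines the study a [simulate_study()] call emits: plate layout and
#' replication, image geometry, the cell model (uniformly placed truncated
#' Gaussian spots with lognormal peak intensities), the camera model
#' (multiplicative shading, additive background folded through the field,
#' dark offset, Gaussian read noise), and treatment effects.
#'
#' The pixel model for each site and channel is
#' `raw = field * (background_level + sum of cell spots) + dark_offset + N(0, read_noise_sd)`,
#' clipped at zero; cell peak intensities are
#' `lognormal(cell_peak_meanlog, cell_peak_sdlog)` scaled by any compound
#' effect, and by `positive_effect_factor` in the readout channel of
#' positive-control wells.
#'
#' @param n_plates Number of plates.
#' @param plate_layout Tibble with `well_row`, `well_col`, `compound`,
#'   `concentration`, `role`, `moa`, applied to each plate
#'   (default [make_plate_layout()]).  An optional `plate` column (values
#'   `"P01"`, `"P02"`, ...) assigns rows to specific plates instead, the
#'   natural design when compounds occupy particular plates of a screen.
#' @param sites_per_well Imaged fields per well.
#' @param channels Channel names; the first is conventionally nuclear.
#' @param nuclear_channel,readout_channel Designated channels.
#' @param image_shape `c(height, width)` in pixels.
#' @param cells_per_image_mean Poisson mean cell count per site.
#' @param cell_radius_px_mean,cell_radius_px_sd Cell spot radius
#'   distribution (truncated normal, minimum 1 px).
#' @param cell_peak_meanlog,cell_peak_sdlog Lognormal peak intensity
#'   parameters (the asymmetric per-cell distributions the one-tailed Z'
#'   accommodates).
#' @param background_level Sample background folded through the field.
#' @param read_noise_sd Gaussian camera noise s.d.
#' @param dark_offset Additive camera offset (default 0: the division-based
#'   correction assumes a purely multiplicative anomaly; a nonzero value
#'   probes model misspecification).
#' @param positive_effect_factor Multiplier on readout-channel cell
#'   intensity in positive-control wells.
#' @param field_kind,field_amplitude,field_width_frac Shading field family
#'   shared by the study.
#' @param fields_differ_by_plate If `TRUE` (default, matching the
#'   observation that ICFs vary significantly across plates) each plate and
#'   channel gets its own field centre/width drawn from the seed; if `FALSE`
#'   all plates share one field per channel.
#' @param effects Named list, per compound: `list(intensity = <named
#'   per-channel factor vector>, area = <scalar area factor>)`.
#' @param seed Master seed; every image derives its own substream from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_plates = 1,
                       plate_layout = make_plate_layout(),
                       sites_per_well = 2,
                       channels = c("DAPI", "tubulin"),
                       nuclear_channel = channels[1],
                       readout_channel = channels[length(channels)],
                       image_shape = c(256, 256),
                       cells_per_image_mean = 40,
                       cell_radius_px_mean = 6,
                       cell_radius_px_sd = 1,
                       cell_peak_meanlog = log(300),
                       cell_peak_sdlog = 0.6,
                       background_level = 50,
                       read_noise_sd = 3,
                       dark_offset = 0,
                       positive_effect_factor = 1.6,
                       field_kind = "gaussian_vignette",
                       field_amplitude = 0.25,
                       field_width_frac = 0.25,
                       fields_differ_by_plate = TRUE,
                       effects = list(),
                       seed = 1) {
  cfg <- list(n_plates = as.integer(n_plates), plate_layout = as_tibble(plate_layout),
              sites_per_well = as.integer(sites_per_well), channels = channels,
              nuclear_channel = nuclear_channel, readout_channel = readout_channel,
              image_shape = as.integer(image_shape),
              cells_per_image_mean = cells_per_image_mean,
              cell_radius_px_mean = cell_radius_px_mean,
              cell_radius_px_sd = cell_radius_px_sd,
              cell_peak_meanlog = cell_peak_meanlog,
              cell_peak_sdlog = cell_peak_sdlog,
              background_level = background_level,
              read_noise_sd = read_noise_sd,
              dark_offset = dark_offset,
              positive_effect_factor = positive_effect_factor,
              field_kind = field_kind,
              field_amplitude = field_amplitude,
              field_width_frac = field_width_frac,
              fields_differ_by_plate = isTRUE(fields_differ_by_plate),
              effects = effects,
              seed = as.integer(seed))
  stopifnot(cfg$n_plates >= 1, cfg$sites_per_well >= 1,
            length(cfg$channels) >= 1, all(cfg$image_shape >= 16))
  if (cfg$cells_per_image_mean < 0 || cfg$background_level < 0 ||
      cfg$read_noise_sd < 0 || cfg$dark_offset < 0) {
    stop_value("rates, levels and noise must be non-negative")
  }
  if (cfg$positive_effect_factor < 1) stop_value("positive_effect_factor must be >= 1")
  need <- c("well_row", "well_col", "compound", "concentration", "role", "moa")
  miss <- setdiff(need, names(cfg$plate_layout))
  if (length(miss) > 0) stop_config(paste0("plate_layout missing column(s): ",
                                           paste(miss, collapse = ", ")))
  structure(cfg, class = "sim_config")
}

#' Default plate layout
#'
#' Wells in column-major order; the first `n_negative` wells are DMSO-like
#' negative controls, the last `n_positive` are positive controls, the rest
#' untreated samples.
#'
#' @param n_rows,n_cols Plate geometry (default 8 x 12, a 96-well plate).
#' @param n_negative,n_positive Number of control wells.
#' @param negative_compound,positive_compound Control compound labels.
#' @return Layout tibble for [sim_config()].
#' @export
make_plate_layout <- function(n_rows = 8, n_cols = 12,
                              n_negative = 8, n_positive = 8,
                              negative_compound = "DMSO",
                              positive_compound = "taxol") {
  n <- n_rows * n_cols
  if (n_negative + n_positive > n) stop_value("more control wells than wells")
  layout <- tibble(
    well_row = rep(LETTERS[seq_len(n_rows)], times = n_cols),
    well_col = rep(seq_len(n_cols), each = n_rows),
    compound = "none", concentration = 0,
    role = "sample", moa = NA_character_
  )
  if (n_negative > 0) {
    idx <- seq_len(n_negative)
    layout$role[idx] <- "negative_control"
    layout$compound[idx] <- negative_compound
  }
  if (n_positive > 0) {
    idx <- n - seq_len(n_positive) + 1
    layout$role[idx] <- "positive_control"
    layout$compound[idx] <- positive_compound
    layout$concentration[idx] <- 1
  }
  layout
}

#' Layout and effects for a mechanism-of-action study
#'
#' Builds a plate layout carrying `n_moas * compounds_per_moa` compounds
#' (each replicated in `wells_per_compound` wells per plate, plus negative
#' control wells for normalization) and a matching `effects` list in which
#' each MOA perturbs a distinct combination of per-channel intensity and
#' cell area, with small deterministic compound-to-compound variation within
#' an MOA.
#'
#' In a multi-plate design (`plates > 1`) each compound is assigned to a
#' single plate, with the compounds of an MOA spread round-robin across
#' plates — the arrangement of real profiling screens, where recognizing an
#' MOA requires comparing profiles *across* plates and hence across
#' plate-specific illumination anomalies.  Every plate carries its own
#' negative-control wells for normalization.
#'
#' @param n_moas Number of mechanism classes.
#' @param compounds_per_moa Compounds per class.
#' @param wells_per_compound Replicate wells per compound (on its plate).
#' @param n_negative Negative-control wells per plate.
#' @param channels Channel names the effects address (first channel, the
#'   nuclear stain, is left unperturbed).
#' @param intensity_up,intensity_down,area_up Effect sizes.
#' @param n_rows Plate rows.
#' @param plates Number of plates to spread compounds over (1 = all
#'   compounds on every plate).
#' @return List with `plate_layout` and `effects`, ready for [sim_config()].
#' @export
moa_study <- function(n_moas = 4, compounds_per_moa = 3, wells_per_compound = 2,
                      n_negative = 8, channels = c("DAPI", "tubulin", "actin"),
                      intensity_up = 1.35, intensity_down = 0.75, area_up = 1.3,
                      n_rows = 8, plates = 1) {
  n_compounds <- n_moas * compounds_per_moa
  moas <- paste0("moa", seq_len(n_moas))
  compounds <- sprintf("cpd%02d", seq_len(n_compounds))
  moa_of <- rep(moas, each = compounds_per_moa)
  perturbable <- setdiff(channels, channels[1])
  effects <- list()
  for (k in seq_len(n_compounds)) {
    m <- (k - 1) %/% compounds_per_moa + 1
    # deterministic within-MOA variation: compounds scaled 0.96 / 1.00 / 1.04
    jit <- 1 + 0.04 * (((k - 1) %% compounds_per_moa) - (compounds_per_moa - 1) / 2)
    intensity <- setNames(rep(1, length(channels)), channels)
    area <- 1
    mode <- (m - 1) %% 4
    if (mode == 0) intensity[perturbable[1]] <- intensity_up * jit
    if (mode == 1) intensity[perturbable[min(2, length(perturbable))]] <- intensity_up * jit
    if (mode == 2) area <- area_up * jit
    if (mode == 3) intensity[perturbable] <- intensity_down / jit
    effects[[compounds[k]]] <- list(intensity = intensity, area = area)
  }
  plate_of <- sprintf("P%02d", ((seq_len(n_compounds) - 1) %% plates) + 1)
  layouts <- lapply(seq_len(plates), function(p) {
    pid <- sprintf("P%02d", p)
    cpds <- compounds[plate_of == pid]
    n_wells_p <- n_negative + length(cpds) * wells_per_compound
    n_cols_p <- ceiling(n_wells_p / n_rows)
    wells <- tibble(
      well_row = rep(LETTERS[seq_len(n_rows)], times = n_cols_p),
      well_col = rep(seq_len(n_cols_p), each = n_rows)
    )[seq_len(n_wells_p), ]
    dplyr::bind_cols(tibble(plate = pid), wells, tibble(
      compound = c(rep("DMSO", n_negative), rep(cpds, each = wells_per_compound)),
      concentration = c(rep(0, n_negative),
                        rep(1, length(cpds) * wells_per_compound)),
      role = c(rep("negative_control", n_negative),
               rep("sample", length(cpds) * wells_per_compound)),
      moa = c(rep(NA_character_, n_negative),
              rep(moa_of[plate_of == pid], each = wells_per_compound))
    ))
  })
  layout <- dplyr::bind_rows(layouts)
  if (plates == 1) layout$plate <- NULL
  list(plate_layout = layout, effects = effects)
}

# deterministic per-site substream seed below 2^31
site_seed <- function(seed, plate_idx, well_idx, site) {
  s <- seed %% 2147483647
  for (k in c(plate_idx, well_idx, site)) {
    s <- (s * 48271 + k) %% 2147483647
  }
  as.integer(s)
}

effect_for <- function(config, compound, role) {
  intensity <- setNames(rep(1, length(config$channels)), config$channels)
  area <- 1
  eff <- config$effects[[compound]]
  if (!is.null(eff)) {
    if (!is.null(eff$intensity)) {
      intensity[names(eff$intensity)] <- unlist(eff$intensity)
    }
    area <- eff$area %||% 1
  }
  if (identical(role, "positive_control")) {
    intensity[config$readout_channel] <-
      intensity[config$readout_channel] * config$positive_effect_factor
  }
  list(intensity = intensity, area = area)
}

# draw a site's shared cell population from the current RNG state
draw_cells <- function(config, area_factor = 1) {
  h <- config$image_shape[1]
  w <- config$image_shape[2]
  n <- rpois(1, config$cells_per_image_mean)
  tibble(
    cell = seq_len(n),
    row = runif(n, 1, h),
    col = runif(n, 1, w),
    radius = pmax(1, rnorm(n, config$cell_radius_px_mean, config$cell_radius_px_sd)) *
      sqrt(area_factor),
    peak = rlnorm(n, config$cell_peak_meanlog, config$cell_peak_sdlog)
  )
}

#' Render one simulated image
#'
#' Renders one channel of one site under the pixel model: cells are
#' truncated Gaussian spots (sigma = radius / 2, truncated at 2.5 sigma)
#' added to a flat background, the sum is multiplied by the shading field,
#' then dark offset and Gaussian read noise are added and the result is
#' clipped at zero.  The returned truth totals are each cell's integrated
#' intensity *before* the field is applied — the quantity a perfectly
#' corrected measurement should recover.
#'
#' @param field Shading field matrix matching `config$image_shape`.
#' @param config A [sim_config()].
#' @param channel Channel to render.
#' @param cells Cell table from the site's shared draw (columns `row`,
#'   `col`, `radius`, `peak`); `NULL` draws a fresh population from the
#'   current RNG state.
#' @param role,compound Well context used to apply treatment effects.
#' @return List with `pixels` (numeric matrix) and `truth` (per-cell true
#'   integrated intensity in this channel).
#' @export
simulate_image <- function(field, config, channel, cells = NULL,
                           role = "sample", compound = "none") {
  h <- config$image_shape[1]
  w <- config$image_shape[2]
  if (!identical(dim(field), c(h, w))) {
    stop_data("field shape does not match config$image_shape")
  }
  eff <- effect_for(config, compound, role)
  if (is.null(cells)) cells <- draw_cells(config, area_factor = eff$area)
  gain <- eff$intensity[[channel]]
  pre <- matrix(config$background_level, h, w)
  truth <- numeric(nrow(cells))
  if (nrow(cells) > 0) {
    for (i in seq_len(nrow(cells))) {
      sig <- cells$radius[i] / 2
      ext <- ceiling(2.5 * sig)
      r0 <- max(1, floor(cells$row[i] - ext)); r1 <- min(h, ceiling(cells$row[i] + ext))
      c0 <- max(1, floor(cells$col[i] - ext)); c1 <- min(w, ceiling(cells$col[i] + ext))
      d2 <- outer((r0:r1 - cells$row[i])^2, (c0:c1 - cells$col[i])^2, "+")
      spot <- cells$peak[i] * gain * exp(-d2 / (2 * sig^2))
      spot[d2 > (2.5 * sig)^2] <- 0
      pre[r0:r1, c0:c1] <- pre[r0:r1, c0:c1] + spot
      truth[i] <- sum(spot)
    }
  }
  raw <- field * pre + config$dark_offset
  if (config$read_noise_sd > 0) {
    raw <- raw + matrix(rnorm(h * w, 0, config$read_noise_sd), h, w)
  }
  list(pixels = pmax(raw, 0), truth = truth)
}

plate_fields <- function(config, plate_idx) {
  base <- field_params(config$field_kind, config$field_amplitude,
                       width_frac = config$field_width_frac)
  params <- list()
  for (ci in seq_along(config$channels)) {
    p <- base
    if (config$fields_differ_by_plate) {
      set.seed(site_seed(config$seed, plate_idx, 0, ci))
      p$centre <- pmin(pmax(p$centre + runif(2, -0.2, 0.2), 0), 1)
      p$width_frac <- p$width_frac * runif(1, 0.85, 1.15)
    }
    params[[config$channels[ci]]] <- p
  }
  params
}

#' Simulate a complete study to disk
#'
#' Writes a multi-plate, multi-well, multi-site, multi-channel image set
#' (16-bit TIFFs plus metadata CSV in the package's schema) together with
#' its ground truth: per-cell true positions, radii and pre-field integrated
#' intensities, the exact shading field of every (plate, channel), and the
#' field parameters.  Every image derives its own RNG substream from
#' `config$seed`, so runs are byte-reproducible and any single image can be
#' regenerated in isolation.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created; must be empty or absent).
#' @param write_truth Also write `truth_cells.csv`, `truth.json` and the
#'   true fields as float TIFFs under `out_dir/truth/`.
#' @return List of class `sim_study`: `images` (image-set tibble), `truth`
#'   (list with `cells`, `fields`, `field_params`, `seed`).
#' @export
simulate_study <- function(config, out_dir, write_truth = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  h <- config$image_shape[1]
  w <- config$image_shape[2]
  records <- list()
  truth_rows <- list()
  fields <- list()
  fp_all <- list()
  for (p in seq_len(config$n_plates)) {
    plate <- sprintf("P%02d", p)
    fps <- plate_fields(config, p)
    fp_all[[plate]] <- fps
    for (ch in config$channels) {
      fields[[paste0(plate, "/", ch)]] <- make_illumination_field(c(h, w), fps[[ch]])
    }
    layout <- config$plate_layout
    if ("plate" %in% names(layout)) {
      layout <- layout[layout$plate == plate, ]
    }
    for (wi in seq_len(nrow(layout))) {
      lay <- layout[wi, ]
      well <- sprintf("%s%02d", lay$well_row, lay$well_col)
      for (s in seq_len(config$sites_per_well)) {
        set.seed(site_seed(config$seed, p, wi, s))
        eff <- effect_for(config, lay$compound, lay$role)
        cells <- draw_cells(config, area_factor = eff$area)
        site_truth <- cells
        for (ch in config$channels) {
          sim <- simulate_image(fields[[paste0(plate, "/", ch)]], config, ch,
                                cells = cells, role = lay$role,
                                compound = lay$compound)
          site_truth[[paste0("true_total_", ch)]] <- sim$truth
          fn <- sprintf("%s_%s_s%d_%s.tiff", plate, well, s, ch)
          write_image_tiff(sim$pixels, file.path(out_dir, fn), bits = 16)
          records[[length(records) + 1]] <- tibble(
            filename = fn, plate = plate,
            well_row = lay$well_row, well_col = lay$well_col, site = s,
            channel = ch, compound = lay$compound,
            concentration = lay$concentration, role = lay$role,
            moa = lay$moa
          )
        }
        if (nrow(site_truth) > 0) {
          truth_rows[[length(truth_rows) + 1]] <- dplyr::bind_cols(
            tibble(plate = plate, well = well, site = s)[rep(1, nrow(site_truth)), ],
            site_truth
          )
        }
      }
    }
  }
  records <- dplyr::bind_rows(records)
  meta_path <- file.path(out_dir, "metadata.csv")
  readr::write_csv(records, meta_path, progress = FALSE)
  truth_cells <- dplyr::bind_rows(truth_rows)
  truth <- list(cells = truth_cells, fields = fields, field_params = fp_all,
                seed = config$seed)
  if (write_truth) {
    tdir <- file.path(out_dir, "truth")
    dir.create(tdir, showWarnings = FALSE)
    readr::write_csv(truth_cells, file.path(tdir, "truth_cells.csv"), progress = FALSE)
    for (key in names(fields)) {
      fn <- paste0("field_", gsub("/", "_", key), ".tiff")
      write_float_tiff(fields[[key]], file.path(tdir, fn))
    }
    jsonlite::write_json(
      list(seed = config$seed,
           field_params = lapply(fp_all, function(fps) lapply(fps, unclass))),
      file.path(tdir, "truth.json"), auto_unbox = TRUE, digits = NA
    )
  }
  structure(list(images = read_image_set(meta_path, out_dir), truth = truth),
            class = "sim_study")
}
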