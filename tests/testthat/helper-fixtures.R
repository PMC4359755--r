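# Small programmatic fixtures shared across test files.

# write a tiny image set (one plate, n wells x 1 site x channels) of given
# constant-value images; returns the image-set tibble
write_tiny_set <- function(dir, n_wells = 4, channels = "DAPI",
                           values = rep(100, n_wells), shape = c(16, 16),
                           bits = 16) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (w in seq_len(n_wells)) {
    for (ch in channels) {
      fn <- sprintf("P01_%s%02d_s1_%s.tiff", LETTERS[w], 1L, ch)
      write_image_tiff(matrix(values[w], shape[1], shape[2]),
                       file.path(dir, fn), bits = bits)
      rows[[length(rows) + 1]] <- tibble::tibble(
        filename = fn, plate = "P01", well_row = LETTERS[w], well_col = 1L,
        site = 1L, channel = ch, compound = "DMSO", concentration = 0,
        role = "negative_control", moa = NA_character_
      )
    }
  }
  meta <- dplyr::bind_rows(rows)
  readr::write_csv(meta, file.path(dir, "metadata.csv"), progress = FALSE)
  read_image_set(file.path(dir, "metadata.csv"), dir)
}

# a smooth positive analytic vignette for smoothing/correction tests
analytic_vignette <- function(shape = c(64, 64), amplitude = 0.2) {
  make_illumination_field(shape, field_params("gaussian_vignette", amplitude))
}

# small simulated study used by several module tests (cached per session)
.tiny_study_cache <- new.env(parent = emptyenv())
tiny_study <- function(seed = 1, ...) {
  key <- paste0(seed, "/", rlang::hash(list(...)))
  if (is.null(.tiny_study_cache[[key]])) {
    args <- utils::modifyList(
      list(plate_layout = make_plate_layout(4, 6, 4, 4),
           sites_per_well = 1, image_shape = c(96, 96),
           cells_per_image_mean = 15, cell_radius_px_mean = 3,
           cell_radius_px_sd = 0.5, seed = seed),
      list(...)
    )
    cfg <- do.call(sim_config, args)
    dir <- file.path(tempdir(), paste0("tiny_study_", gsub("[^0-9a-z]", "", key)))
    .tiny_study_cache[[key]] <- simulate_study(cfg, dir, write_truth = FALSE)
  }
  .tiny_study_cache[[key]]
}
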