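test_that("generated fields meet the min/max contract for all kinds", {
  for (kind in c("gaussian_vignette", "planar_gradient", "off_axis_blob")) {
    for (amp in c(0.1, 0.25, 0.3, 0.5)) {
      f <- make_illumination_field(c(40, 56), field_params(kind, amp))
      expect_equal(max(f), 1, tolerance = 1e-6)
      expect_equal(min(f), 1 - amp, tolerance = 1e-6)
    }
  }
  # amplitude 0 is a flat field, 0.25 gives variation_percent 25
  expect_equal(make_illumination_field(c(8, 8), field_params(amplitude = 0)),
               matrix(1, 8, 8))
  f25 <- make_illumination_field(c(64, 64), field_params(amplitude = 0.25))
  expect_equal(variation_percent(f25), 25, tolerance = 1e-4)
  # determinism: same params, same shape, bit-identical
  expect_identical(f25, make_illumination_field(c(64, 64), field_params(amplitude = 0.25)))
  expect_error(field_params(amplitude = 0.6), class = "illumfield_value_error")
})

test_that("simulate_image follows the pixel model exactly in the noise-free limit", {
  cfg <- sim_config(image_shape = c(32, 32), cells_per_image_mean = 0,
                    read_noise_sd = 0, dark_offset = 7, background_level = 40)
  f <- make_illumination_field(c(32, 32), field_params(amplitude = 0.2))
  sim <- simulate_image(f, cfg, "DAPI",
                        cells = tibble::tibble(cell = integer(0), row = numeric(0),
                                               col = numeric(0), radius = numeric(0),
                                               peak = numeric(0)))
  expect_equal(sim$pixels, f * 40 + 7)
  # determinism under a fixed RNG state
  cfg2 <- sim_config(image_shape = c(32, 32), cells_per_image_mean = 10)
  set.seed(99)
  a <- simulate_image(f, cfg2, "DAPI")
  set.seed(99)
  b <- simulate_image(f, cfg2, "DAPI")
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$truth, b$truth)
})

test_that("the mean of many simulated images recovers the field", {
  # background-dominated regime: dim cells, so the pixel-model expectation
  # is tight enough for a 2% max-error bound
  cfg <- sim_config(image_shape = c(48, 48), cells_per_image_mean = 8,
                    cell_radius_px_mean = 2, cell_radius_px_sd = 0.3,
                    read_noise_sd = 2, cell_peak_meanlog = log(30))
  f <- make_illumination_field(c(48, 48), field_params(amplitude = 0.25))
  set.seed(123)
  n <- 500
  acc <- matrix(0, 48, 48)
  ex_cells <- 0
  for (i in seq_len(n)) {
    sim <- simulate_image(f, cfg, "DAPI")
    acc <- acc + sim$pixels
    ex_cells <- ex_cells + sum(sim$truth)
  }
  mp <- acc / n
  # analytic expectation away from the border (cell light is uniform in
  # expectation only where a full spot fits inside the frame)
  expected <- f * (cfg$background_level + ex_cells / n / (48 * 48))
  inner <- 8:40
  expect_lt(max(abs(mp[inner, inner] - expected[inner, inner]) /
                  expected[inner, inner]), 0.02)
})

test_that("simulate_study writes a complete, reproducible study", {
  cfg <- sim_config(plate_layout = make_plate_layout(4, 6, 4, 4),
                    n_plates = 2, sites_per_well = 2,
                    channels = c("DAPI", "tubulin", "actin"),
                    image_shape = c(48, 48), cells_per_image_mean = 5, seed = 11)
  d1 <- withr::local_tempdir()
  st <- simulate_study(cfg, d1)
  # 2 plates x 24 wells x 2 sites x 3 channels
  expect_equal(nrow(st$images), 2 * 24 * 2 * 3)
  expect_equal(nrow(dplyr::distinct(st$images[, c("plate", "well", "site")])), 96)
  # truth covers every site with cells and both field entries exist
  expect_equal(length(st$truth$fields), 6)
  expect_true(all(c("truth_cells.csv", "truth.json") %in%
                  list.files(file.path(d1, "truth"))))
  # byte-identical metadata and truth across runs with the same seed
  d2 <- withr::local_tempdir()
  simulate_study(cfg, d2)
  expect_identical(readBin(file.path(d1, "metadata.csv"), "raw", 1e6),
                   readBin(file.path(d2, "metadata.csv"), "raw", 1e6))
  expect_identical(readBin(file.path(d1, "truth", "truth_cells.csv"), "raw", 1e7),
                   readBin(file.path(d2, "truth", "truth_cells.csv"), "raw", 1e7))
  # per-plate fields differ under the default jitter
  expect_gt(max(abs(st$truth$fields[["P01/DAPI"]] - st$truth$fields[["P02/DAPI"]])), 0.01)
})

test_that("pooled cell centres are uniform across the field of view", {
  passes <- 0
  for (seed in 1:20) {
    cfg <- sim_config(plate_layout = make_plate_layout(2, 2, 2, 2),
                      sites_per_well = 4, channels = "DAPI",
                      image_shape = c(64, 64), cells_per_image_mean = 40,
                      seed = seed)
    d <- file.path(tempdir(), paste0("unif", seed))
    st <- simulate_study(cfg, d, write_truth = FALSE)
    cells <- st$truth$cells
    gr <- cut(cells$row, breaks = seq(0.5, 64.5, length.out = 5))
    gc <- cut(cells$col, breaks = seq(0.5, 64.5, length.out = 5))
    p <- suppressWarnings(stats::chisq.test(table(gr, gc))$p.value)
    if (p > 0.01) passes <- passes + 1
    unlink(d, recursive = TRUE)
  }
  expect_gte(passes, 18)
})

test_that("measured totals on corrected images track the simulated truth", {
  st <- tiny_study(seed = 9, cells_per_image_mean = 8, read_noise_sd = 1,
                   cell_radius_px_mean = 4, cell_radius_px_sd = 0.5,
                   fields_differ_by_plate = FALSE)
  icfs <- estimate_icfs(st$images, window_px = "auto")
  out <- withr::local_tempdir()
  corrected <- correct_batch(st$images, icfs, out_dir = out)
  cells <- measure_image_set(corrected, "DAPI", min_area_px = 10)
  truth <- st$truth$cells
  # match measured cells to truth by nearest centre within each site
  matched <- dplyr::inner_join(
    cells, truth,
    by = c("plate" = "plate", "well" = "well", "site" = "site"),
    relationship = "many-to-many"
  )
  matched <- matched |>
    dplyr::mutate(d2 = (centroid_row + 1 - row)^2 + (centroid_col + 1 - col)^2) |>
    dplyr::group_by(plate, well, site, cell_id) |>
    dplyr::slice_min(d2, n = 1, with_ties = FALSE) |>
    dplyr::filter(d2 < 16) |>
    dplyr::ungroup()
  expect_gt(nrow(matched), 80)
  # the background-subtracted cell signal tracks the pre-field truth;
  # rank correlation, since threshold truncation makes the mapping from true
  # to measured integral monotone but not linear
  signal <- matched$total_DAPI - 50 * matched$area_px
  expect_gt(cor(signal, matched$true_total_DAPI, method = "spearman"), 0.95)
})
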