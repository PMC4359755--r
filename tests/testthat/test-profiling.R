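test_that("segment_cells finds isolated bright objects and ignores blanks", {
  blank <- matrix(50, 64, 64)
  expect_equal(max(segment_cells(blank)), 0)
  # one bright 10x10 square -> one label of (approximately) its area; the
  # Gaussian pre-smoothing erodes the hard edge slightly
  sq <- matrix(10, 64, 64)
  sq[20:29, 30:39] <- 500
  lab <- segment_cells(sq, min_area_px = 20)
  expect_equal(max(lab), 1)
  expect_gte(sum(lab == 1), 64)
  expect_lte(sum(lab == 1), 144)
  # well-separated simulated discs are counted exactly
  set.seed(4)
  img <- matrix(20, 96, 96)
  centres <- cbind(c(15, 15, 48, 80, 80), c(15, 80, 48, 15, 80))
  for (i in 1:5) {
    d2 <- outer((1:96 - centres[i, 1])^2, (1:96 - centres[i, 2])^2, "+")
    img <- img + 400 * exp(-d2 / (2 * 9))
  }
  expect_equal(max(segment_cells(img, min_area_px = 10)), 5)
  # 8-connectivity: a diagonal chain is one object
  diag_img <- matrix(0, 32, 32)
  for (k in 10:20) diag_img[k, k] <- 100
  lab8 <- illumfield:::label_components8(diag_img > 0)
  expect_equal(max(lab8), 1)
})

test_that("measure_cells computes exact per-label sums and means", {
  labels <- matrix(0L, 8, 8)
  labels[2:4, 2:4] <- 1L
  labels[6:7, 6:8] <- 2L
  chans <- list(a = matrix(2, 8, 8), b = matrix(1:64, 8, 8) * 1.0)
  rows <- measure_cells(labels, chans)
  expect_equal(nrow(rows), 2)
  expect_equal(rows$area_px, c(9L, 6L))
  expect_equal(rows$total_a, c(18, 12))
  expect_equal(rows$mean_a, c(2, 2))
  expect_equal(rows$total_b, c(sum(chans$b[labels == 1L]), sum(chans$b[labels == 2L])))
  # empty mask -> empty table with the full schema
  empty <- measure_cells(matrix(0L, 8, 8), chans["a"])
  expect_equal(nrow(empty), 0)
  expect_true(all(c("cell_id", "area_px", "total_a", "mean_a") %in% names(empty)))
  expect_error(measure_cells(labels, list(a = matrix(0, 4, 4))),
               class = "illumfield_data_error")
})

make_cells <- function(n_per_group, plates = "P01") {
  purrr::map_dfr(plates, function(p) {
    set.seed(match(p, plates))
    tibble::tibble(
      plate = p,
      well = rep(c("A01", "B01", "C01", "D01"), each = n_per_group),
      site = 1L,
      compound = rep(c("DMSO", "DMSO", "cpd1", "cpd2"), each = n_per_group),
      concentration = rep(c(0, 0, 1, 1), each = n_per_group),
      role = rep(c("negative_control", "negative_control", "sample", "sample"),
                 each = n_per_group),
      moa = rep(c(NA, NA, "m1", "m2"), each = n_per_group),
      cell_id = seq_len(4 * n_per_group),
      area_px = pmax(5L, rpois(4 * n_per_group, 50)),
      total_ch = rlnorm(4 * n_per_group, 5, 0.3),
      mean_ch = rlnorm(4 * n_per_group, 1, 0.2)
    )
  })
}

test_that("normalize_features z-scores against plate controls", {
  cells <- make_cells(60)
  norm <- normalize_features(cells)
  ctrl <- norm[norm$role == "negative_control", ]
  for (f in c("area_px", "total_ch", "mean_ch")) {
    expect_equal(mean(ctrl[[f]]), 0, tolerance = 1e-10)
    expect_equal(sd(ctrl[[f]]), 1, tolerance = 1e-10)
  }
  # a cell sitting at the control mean maps to 0
  cells2 <- cells
  cells2$total_ch[cells2$role == "sample"][1] <-
    mean(cells$total_ch[cells$role == "negative_control"])
  norm2 <- normalize_features(cells2)
  expect_equal(norm2$total_ch[norm2$role == "sample"][1], 0, tolerance = 1e-10)
  # constant-in-controls feature is dropped study-wide with a warning
  cells3 <- cells
  cells3$area_px[cells3$role == "negative_control"] <- 42L
  expect_warning(norm3 <- normalize_features(cells3), "area_px")
  expect_false("area_px" %in% names(norm3))
  # plate without controls errors
  cells4 <- cells
  cells4$role[cells4$role == "negative_control"] <- "sample"
  expect_error(suppressWarnings(normalize_features(cells4)),
               class = "illumfield_value_error")
})

test_that("treatment_profiles averages cells per treatment", {
  cells <- make_cells(20)
  prof <- treatment_profiles(normalize_features(cells))
  expect_equal(nrow(prof), 3)  # DMSO, cpd1, cpd2
  expect_equal(sum(prof$n_cells), nrow(cells))
  # direct mean check on one treatment/feature
  norm <- normalize_features(cells)
  expect_equal(prof$total_ch[prof$compound == "cpd1"],
               mean(norm$total_ch[norm$compound == "cpd1"]))
  # invariant to cell row order
  shuffled <- norm[sample(nrow(norm)), ]
  expect_equal(treatment_profiles(shuffled), prof)
})

orthogonal_profiles <- function(n_moas = 3, per_moa = 2, noise = 0.01, seed = 5) {
  set.seed(seed)
  purrr::map_dfr(seq_len(n_moas), function(m) {
    purrr::map_dfr(seq_len(per_moa), function(k) {
      v <- rep(0, n_moas) + rnorm(n_moas, 0, noise)
      v[m] <- v[m] + 1
      out <- tibble::tibble(compound = sprintf("c%d_%d", m, k), concentration = 1,
                            moa = paste0("moa", m), n_cells = 100L)
      for (j in seq_len(n_moas)) out[[paste0("total_f", j)]] <- v[j]
      out
    })
  })
}

test_that("nn_classify_loco classifies and matches the brute-force oracle", {
  # two compounds, same MOA, identical vectors -> perfect
  prof <- tibble::tibble(compound = c("a", "b"), concentration = 1,
                         moa = "m", n_cells = 10L,
                         total_x = c(1, 1), total_y = c(2, 2))
  expect_equal(nn_classify_loco(prof)$accuracy, 100)
  # orthogonal MOA corners with small noise -> perfect, and oracle-identical
  prof2 <- orthogonal_profiles()
  res <- nn_classify_loco(prof2)
  expect_equal(res$accuracy, 100)
  expect_equal(res$predictions$moa_predicted, nn_oracle(prof2))
  # row sums match per-MOA treatment counts
  expect_equal(unname(rowSums(res$counts)),
               as.vector(table(factor(prof2$moa, levels = res$labels))))
  # single compound -> value error
  expect_error(nn_classify_loco(prof[1, ]), class = "illumfield_value_error")
})

test_that("nn_classify_loco agrees with the oracle on random instances", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(6:20, 1)
    prof <- tibble::tibble(
      compound = paste0("c", sample(ceiling(n / 2), n, replace = TRUE)),
      concentration = sample(c(1, 3), n, replace = TRUE),
      moa = paste0("m", sample(3, n, replace = TRUE)),
      n_cells = 10L
    )
    # ensure uniqueness of (compound, concentration) and >= 2 compounds
    prof <- dplyr::distinct(prof, compound, concentration, .keep_all = TRUE)
    if (length(unique(prof$compound)) < 2) next
    for (j in 1:4) prof[[paste0("total_f", j)]] <- rnorm(nrow(prof))
    for (metric in c("cosine", "euclidean")) {
      res <- nn_classify_loco(prof, metric = metric)
      expect_equal(res$predictions$moa_predicted, nn_oracle(prof, metric))
    }
  }
})

test_that("accuracy is invariant to profile order and MOA relabelling", {
  prof <- orthogonal_profiles(n_moas = 4, per_moa = 3, noise = 0.3, seed = 9)
  base <- nn_classify_loco(prof)
  shuffled <- prof[sample(nrow(prof)), ]
  expect_equal(nn_classify_loco(shuffled)$accuracy, base$accuracy)
  relabel <- prof
  relabel$moa <- paste0("X_", relabel$moa)
  expect_equal(nn_classify_loco(relabel)$accuracy, base$accuracy)
})

test_that("per-plate affine intensity distortion does not change accuracies", {
  cells <- make_cells(40, plates = c("P01", "P02"))
  chain <- function(cc) {
    norm <- normalize_features(cc)
    nn_classify_loco(treatment_profiles(norm[norm$role == "sample", ]))$accuracy
  }
  base <- chain(cells)
  warped <- cells
  for (p in unique(cells$plate)) {
    a <- if (p == "P01") 2.5 else 0.6
    b <- if (p == "P01") 30 else -1
    idx <- warped$plate == p
    for (f in c("area_px", "total_ch", "mean_ch")) {
      warped[[f]][idx] <- a * warped[[f]][idx] + b
    }
  }
  expect_equal(chain(warped), base)
})

test_that("compare_correction_effect is deterministic and checks metadata", {
  ms <- moa_study(n_moas = 2, compounds_per_moa = 2, wells_per_compound = 1,
                  n_negative = 6, channels = c("DAPI", "tubulin"),
                  n_rows = 5)
  cfg <- sim_config(plate_layout = ms$plate_layout, effects = ms$effects,
                    sites_per_well = 1, image_shape = c(96, 96),
                    cells_per_image_mean = 20, seed = 6)
  st <- simulate_study(cfg, withr::local_tempdir(), write_truth = FALSE)
  cmp <- suppressWarnings(
    compare_correction_effect(st$images, st$images, "DAPI")
  )
  expect_equal(cmp$accuracy_uncorrected, cmp$accuracy_corrected)
  broken <- st$images
  broken$compound[broken$role == "sample"][1] <- "other"
  expect_error(compare_correction_effect(st$images, broken, "DAPI"),
               class = "illumfield_data_error")
})
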