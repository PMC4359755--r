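test_that("mean_projection averages pixelwise in double precision", {
  a <- matrix(2, 4, 4)
  b <- matrix(4, 4, 4)
  expect_equal(mean_projection(list(a, b)), matrix(3, 4, 4))
  expect_equal(mean_projection(list(a)), a)
  # no accumulator overflow at full 16-bit scale
  big <- replicate(1000, matrix(65535, 2, 2), simplify = FALSE)
  expect_equal(mean_projection(big), matrix(65535, 2, 2))
  expect_error(mean_projection(list()), class = "illumfield_value_error")
  expect_error(mean_projection(list(a, matrix(1, 3, 4))),
               class = "illumfield_data_error")
})

test_that("median_smooth matches the brute-force oracle and honours its contract", {
  # constant field and degenerate window are identities
  expect_equal(median_smooth(matrix(7, 5, 5), 3), matrix(7, 5, 5))
  x <- matrix(runif(25), 5, 5)
  expect_equal(median_smooth(x, 1), x)
  # single bright pixel in a field of ones, window 3: oracle-derived medians
  spike <- matrix(1, 5, 5)
  spike[3, 3] <- 100
  expect_equal(median_smooth(spike, 3), median_filter_oracle(spike, 3))
  # the bright pixel never survives a window-3 median
  expect_true(all(median_smooth(spike, 3) == 1))
  # contract violations
  expect_error(median_smooth(x, 2), class = "illumfield_value_error")
  expect_error(median_smooth(x, 7), class = "illumfield_value_error")
})

test_that("median_smooth agrees exactly with the oracle on random images", {
  set.seed(11)
  for (rep in 1:25) {
    h <- sample(3:16, 1)
    w <- sample(3:16, 1)
    x <- matrix(as.numeric(sample(0:255, h * w, replace = TRUE)), h, w)
    for (win in c(1, 3, 5)) {
      if (win > min(h, w)) next
      expect_identical(median_smooth(x, win), median_filter_oracle(x, win))
    }
  }
  # and on float images
  for (rep in 1:3) {
    x <- matrix(rnorm(15 * 12), 15, 12)
    expect_identical(median_smooth(x, 5), median_filter_oracle(x, 5))
  }
})

test_that("median_smooth is monotone in its input", {
  set.seed(12)
  for (rep in 1:10) {
    a <- matrix(runif(100), 10, 10)
    b <- a + matrix(runif(100, 0, 0.5), 10, 10)
    expect_true(all(median_smooth(a, 3) <= median_smooth(b, 3)))
  }
})

test_that("rescale_icf divides out the minimum", {
  expect_equal(rescale_icf(matrix(5, 3, 3)), matrix(1, 3, 3))
  expect_equal(rescale_icf(matrix(c(2, 4), 1, 2)), matrix(c(1, 2), 1, 2))
  withzero <- matrix(c(0, 1, 2, 3), 2, 2)
  expect_error(rescale_icf(withzero), class = "illumfield_data_error")
})

test_that("estimate_icf recovers an already-smooth field from identical images", {
  dir <- withr::local_tempdir()
  # an off-axis hot spot over a flat plateau: the plateau pins the rescaling
  # minimum without border bias, so away from the border the estimate must
  # track the field to sub-0.1% accuracy
  f <- make_illumination_field(c(64, 64),
                               field_params("off_axis_blob", 0.2,
                                            width_frac = 0.3)) * 80
  images <- write_tiny_set(dir, n_wells = 6, values = rep(1, 6), shape = c(64, 64))
  for (p in images$path) write_image_tiff(f, p, bits = 32)
  icf <- estimate_icf(images, "DAPI", window_px = 3)
  truth <- f / min(f)
  m <- 6
  inner <- function(x) x[m:(64 - m), m:(64 - m)]
  expect_lt(max(abs(inner(icf$pixels) - inner(truth)) / inner(truth)), 1e-3)
  expect_equal(min(icf$pixels), 1, tolerance = 1e-9)
  expect_equal(icf$n_images, 6L)
})

test_that("estimate_icfs partitions by group and channel", {
  st <- tiny_study(seed = 1)
  two_plate <- dplyr::mutate(st$images,
    plate = ifelse(.data$well_col <= 3, "P01", "P02"))
  attr(two_plate, "image_root") <- attr(st$images, "image_root")
  icfs <- estimate_icfs(two_plate, window_px = 25)
  expect_equal(length(icfs), 2 * length(unique(st$images$channel)))
  expect_setequal(names(icfs),
                  as.vector(outer(c("P01", "P02"), unique(st$images$channel),
                                  paste, sep = "/")))
})

test_that("estimate_icf is permutation-invariant and scale-equivariant", {
  st <- tiny_study(seed = 2)
  icf <- estimate_icf(st$images, "DAPI", window_px = 25)
  shuffled <- st$images[sample(nrow(st$images)), ]
  attr(shuffled, "image_root") <- attr(st$images, "image_root")
  expect_equal(estimate_icf(shuffled, "DAPI", window_px = 25)$pixels, icf$pixels)
  # multiplying every image by a constant leaves the rescaled ICF unchanged
  dir <- withr::local_tempdir()
  recs <- st$images[st$images$channel == "DAPI", ]
  for (i in seq_len(nrow(recs))) {
    write_image_tiff(load_image(recs[i, ]) * 3.7,
                     file.path(dir, recs$filename[i]), bits = 32)
  }
  scaled <- recs
  scaled$path <- file.path(dir, recs$filename)
  icf_scaled <- estimate_icf(scaled, "DAPI", window_px = 25)
  expect_equal(icf_scaled$pixels, icf$pixels, tolerance = 1e-5)
})

test_that("window defaults and the selection heuristic follow the stated ladder", {
  # canonical acquisition gets the published window (odd-standardized)
  expect_equal(default_window_px(c(1024, 1280)), 501L)
  expect_equal(default_window_px(c(1280, 1024)), 501L)
  # otherwise 40% of the shorter dimension, odd
  expect_equal(default_window_px(c(256, 256)), 103L)
  # candidate ladder for a 1024-px shorter dimension: starts at odd(256),
  # steps by ~102 px
  cands <- illumfield:::window_candidates(1024)
  expect_equal(cands[1], 257L)
  expect_equal(cands[2] - cands[1], 102L)
  # perfectly smooth mean image: first candidate already passes
  f <- analytic_vignette(c(96, 96), 0.2) * 50
  w <- select_window_size(f)
  expect_equal(as.integer(w), illumfield:::window_candidates(96)[1])
  expect_true(attr(w, "converged"))
})

test_that("select_window_size matches an exhaustive candidate sweep", {
  st <- tiny_study(seed = 2)
  recs <- st$images[st$images$channel == "DAPI", ]
  mp <- mean_projection(lapply(seq_len(nrow(recs)),
                               function(i) load_image(recs[i, ])))
  tol <- 0.01
  chosen <- select_window_size(mp, roughness_tol = tol)
  cands <- illumfield:::window_candidates(min(dim(mp)))
  rough <- vapply(cands, function(w) roughness_metric(median_smooth(mp, w)),
                  numeric(1))
  passing <- cands[rough <= tol]
  if (length(passing) > 0) {
    expect_equal(as.integer(chosen), passing[1])
    expect_lte(attr(chosen, "roughness"), tol)
    expect_true(attr(chosen, "converged"))
  } else {
    expect_equal(as.integer(chosen), cands[length(cands)])
    expect_false(attr(chosen, "converged"))
  }
})
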