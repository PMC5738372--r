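test_that("local attenuation map recovers exact slopes on noiseless columns", {
  z <- (0:63) * 0.004
  col <- 100 * exp(-2 * z)
  b <- bscan(matrix(col, 64, 20), 4, 10)
  m <- local_attenuation_map(b, 15)
  expect_equal(mean(m[20:45, ]), -2, tolerance = 1e-6)
  # constant column -> slope 0
  bc <- bscan(matrix(5, 64, 20), 4, 10)
  expect_lt(max(abs(local_attenuation_map(bc, 15))), 1e-9)
  expect_error(local_attenuation_map(b, 14), class = "invalid_parameter")
  expect_error(local_attenuation_map(b, 101), class = "invalid_parameter")
})

test_that("attenuation map contrasts two bands across the boundary row", {
  z <- (0:99) * 0.004
  col <- c(100 * exp(-4 * z[1:50]),
           100 * exp(-4 * z[50]) * exp(-1 * (z[51:100] - z[50])))
  b <- bscan(matrix(col, 100, 16), 4, 10)
  m <- local_attenuation_map(b, 11)
  expect_lt(mean(m[20:40, ]), -3.5)
  expect_gt(mean(m[65:90, ]), -1.5)
})

test_that("minimum-cost path search matches exhaustive enumeration", {
  set.seed(77)
  for (i in 1:12) {
    m <- matrix(runif(64), 8, 8)
    bd <- detect_dej(m, r_max = 1, lateral_smooth_cols = 1)
    oracle <- enumerate_min_path(dej_cost_matrix(m), r_max = 1)
    expect_equal(bd$path_cost, oracle, tolerance = 1e-9)
    expect_true(all(abs(diff(bd$rows)) <= 1))
  }
})

test_that("path search finds a planted flat gradient ridge and rejects flat input", {
  col <- c(rep(10, 30), rep(2, 34))
  b <- bscan(matrix(col, 64, 40) + 0, 4, 10)
  bd <- detect_dej(b, r_max = 2)
  expect_true(all(abs(bd$rows - 30) <= 1))
  expect_error(detect_dej(matrix(1, 32, 32)), class = "no_boundary_contrast")
})

test_that("boundary smoothing lowers total variation and keeps fixed points", {
  sq <- structure(list(rows = rep(c(100L, 120L), each = 10, length.out = 120),
                       confidence = 0.5, r_max = 30L),
                  class = "layer_boundary")
  sm <- smooth_boundary(sq, 15)
  expect_lt(sum(abs(diff(sm$rows))), sum(abs(diff(sq$rows))))
  expect_identical(smooth_boundary(sq, 1)$rows, sq$rows)
  flat <- structure(list(rows = rep(55L, 50), confidence = 1, r_max = 2L),
                    class = "layer_boundary")
  expect_identical(smooth_boundary(flat, 9)$rows, flat$rows)
})

test_that("model-based segmentation recovers a flat boundary on clean scans", {
  spec <- synthetic_spec(surface_row = 40, epidermis_thickness_um = 640,
                         boundary_amplitude_px = 0, speckle_contrast = 0,
                         seed = 1)
  g <- generate_bscan(spec)
  seg <- segment_bscan(g$bscan)
  expect_true(all(abs(seg$boundary$rows - g$truth$boundary) <= 1))
  expect_equal(seg$mu_epidermis_per_mm, 3, tolerance = 0.02)
  expect_equal(seg$mu_dermis_per_mm, 1.5, tolerance = 0.02)
})

test_that("segmentation tracks an undulating DEJ under speckle", {
  maes <- vapply(1:4, function(s) {
    g <- generate_bscan(sinusoid_spec(s))
    seg <- segment_bscan(g$bscan)
    mean(abs(seg$boundary$rows - g$truth$boundary))
  }, numeric(1))
  expect_lt(mean(maes), 4)
})

test_that("layer masks partition the sub-surface image and ROIs are centered", {
  b <- bscan(matrix(runif(600 * 300), 300, 600), 4, 10)
  bd <- structure(list(rows = rep(101L, 600), confidence = 1, r_max = 2L),
                  class = "layer_boundary")
  out <- layer_masks_and_rois(b, bd, surface_row = 1, n_rois = 10,
                              roi_height_px = 64, roi_width_px = 64)
  expect_false(any(out$epidermis_mask & out$dermis_mask))
  expect_true(all(out$epidermis_mask | out$dermis_mask))
  # interior ROIs sit at the evenly distributed centers floor((k-0.5)W/n)+1
  col_k <- as.integer(floor((1:10 - 0.5) * 600 / 10) + 1)
  centers <- vapply(out$rois[2:9], function(r) r$left_col + 32L, integer(1))
  expect_equal(centers, col_k[2:9])
  # epidermis band rows 1..100, roi height 64 -> rows 19..82
  expect_equal(out$rois[[1]]$top_row, 19L)
  expect_equal(out$rois[[1]]$height_px, 64L)
  expect_true(all(vapply(out$rois[1:10], function(r)
    r$top_row + r$height_px - 1L, integer(1)) <= 100L))
  # single ROI per layer, centered in the frame
  out1 <- layer_masks_and_rois(b, bd, 1, n_rois = 1, roi_height_px = 64,
                               roi_width_px = 64)
  expect_length(out1$rois, 2L)
  expect_equal(out1$rois[[1]]$left_col + 32L, as.integer(floor(0.5 * 600) + 1))
})

test_that("thin layer bands shrink ROIs with a warning or error out", {
  b <- bscan(matrix(runif(100 * 64), 100, 64), 4, 10)
  bd <- structure(list(rows = rep(21L, 64), confidence = 1, r_max = 2L),
                  class = "layer_boundary")
  expect_warning(out <- layer_masks_and_rois(b, bd, 1, n_rois = 2,
                                             roi_height_px = 40,
                                             roi_width_px = 16),
                 "thinner")
  expect_equal(out$rois[[1]]$height_px, 20L)
  bd2 <- structure(list(rows = rep(3L, 64), confidence = 1, r_max = 2L),
                   class = "layer_boundary")
  expect_error(suppressWarnings(
    layer_masks_and_rois(b, bd2, 1, n_rois = 2, roi_height_px = 10,
                         roi_width_px = 16)),
    class = "degenerate_layer")
})
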