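test_that("A-scan generator follows the closed-form exponential decay", {
  # no decay, no noise -> constant at surface intensity
  a <- generate_ascan(0, 42, 32, 10, speckle_contrast = 0, n_realizations = 2)
  expect_equal(as.numeric(a), rep(42, 64))
  # mu = 2/mm, I0 = 100: intensity at z = 0.5 mm is 100 exp(-1)
  a2 <- generate_ascan(2, 100, 200, 10, speckle_contrast = 0)
  expect_equal(a2[51, 1], 100 * exp(-1), tolerance = 1e-12)
  expect_error(generate_ascan(2, 100, 4, 10), class = "invalid_parameter")
  expect_error(generate_ascan(2, 100, 64, -1), class = "invalid_parameter")
})

test_that("speckled A-scan stack is unit-mean around the noiseless curve", {
  clean <- generate_ascan(2, 100, 200, 10, speckle_contrast = 0)[, 1]
  stack <- generate_ascan(2, 100, 200, 10, speckle_contrast = 0.3,
                          n_realizations = 500, seed = 3)
  rel <- abs(rowMeans(stack) - clean) / clean
  expect_lt(mean(rel), 0.03)
  # reproducible per seed
  stack2 <- generate_ascan(2, 100, 200, 10, speckle_contrast = 0.3,
                           n_realizations = 500, seed = 3)
  expect_identical(stack, stack2)
})

test_that("speckle field is unit-mean, seeded, with the requested grain size", {
  f <- generate_speckle_field(256, 256, 3, contrast = 0.3, seed = 11)
  expect_equal(mean(f), 1, tolerance = 1e-12)
  expect_true(all(f > 0))
  expect_identical(f, generate_speckle_field(256, 256, 3, contrast = 0.3, seed = 11))
  # near-white field: negligible neighbor correlation
  f0 <- generate_speckle_field(128, 128, 1e-6, contrast = 0.3, seed = 2)
  expect_lt(abs(cor(as.numeric(f0[, -1]), as.numeric(f0[, -128]))), 0.05)
  expect_error(generate_speckle_field(4, 4, 2), class = "invalid_parameter")
})

test_that("B-scan generator plants the requested layer attenuation", {
  spec <- synthetic_spec(mu_epidermis_per_mm = 3, mu_dermis_per_mm = 1,
                         speckle_contrast = 0.2, boundary_amplitude_px = 0,
                         epidermis_thickness_um = 200, seed = 2)
  gb <- generate_bscan(spec)
  epi_px <- 200 / 4
  expect_true(all(gb$truth$boundary == 40 + epi_px))
  expect_equal(gb$truth$class_label, "healthy")
  expect_true(all(gb$truth$lesion_mask == 0))
  # column-averaged epidermis band regresses to the planted mu within 10%
  band <- (40 + 1):(40 + epi_px - 1)
  prof <- rowMeans(gb$bscan$pixels[band, ])
  z <- (seq_along(prof) - 1) * 0.004
  slope <- stats::coef(stats::lm(log(prof) ~ z))[[2]]
  expect_lt(abs(slope - (-3)) / 3, 0.10)
})

test_that("B-scan generation is deterministic and validates lesions", {
  spec <- synthetic_spec(seed = 9)
  expect_identical(generate_bscan(spec)$bscan$pixels,
                   generate_bscan(spec)$bscan$pixels)
  expect_error(synthetic_spec(lesion = list(center_rowcol = c(500, 300),
                                            semi_axes_px = c(40, 40),
                                            mu_lesion_per_mm = 2)),
               class = "invalid_parameter")
  expect_error(synthetic_spec(epidermis_thickness_um = 3000),
               class = "invalid_parameter")
})

test_that("cohort generator yields a balanced, labeled, seed-stable set", {
  specs <- cohort_specs()
  coh <- generate_cohort(specs$healthy, specs$lesion, n_per_class = 3, seed = 5)
  expect_length(coh, 6L)
  labels <- vapply(coh, function(x) x$truth$class_label, character(1))
  expect_equal(sum(labels == "healthy"), 3L)
  expect_equal(sum(labels == "lesion"), 3L)
  lesion_px <- vapply(coh, function(x) sum(x$truth$lesion_mask), numeric(1))
  expect_true(all(lesion_px[labels == "lesion"] > 0))
  expect_true(all(lesion_px[labels == "healthy"] == 0))
  coh2 <- generate_cohort(specs$healthy, specs$lesion, n_per_class = 3, seed = 5)
  expect_identical(coh[[4]]$bscan$pixels, coh2[[4]]$bscan$pixels)
})

test_that("ground-truth boundary marks exactly where the attenuation switches", {
  spec <- synthetic_spec(boundary_amplitude_px = 15, seed = 3,
                         speckle_contrast = 0)
  gb <- generate_bscan(spec)
  mu <- gb$truth$mu_map
  for (cc in c(1, 150, 300, 599)) {
    b <- gb$truth$boundary[cc]
    expect_equal(mu[b - 1, cc], spec$mu_epidermis_per_mm)
    expect_equal(mu[b, cc], spec$mu_dermis_per_mm)
  }
})
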