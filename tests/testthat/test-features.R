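test_that("A-scan averaging over an ROI is plain column-wise arithmetic", {
  px <- matrix(0, 16, 16)
  px[1:3, 1] <- c(2, 4, 6); px[1:3, 2] <- c(4, 8, 10)
  b <- bscan(px, 4, 10)
  prof <- average_ascan_profile(b, roi(1, 1, 3, 2))
  expect_equal(prof$intensities, c(3, 6, 8))
  one <- average_ascan_profile(b, roi(1, 2, 8, 1))
  expect_equal(one$intensities, px[1:8, 2])
  blog <- bscan(px, 4, 10, intensity_domain = "log")
  expect_error(average_ascan_profile(blog, roi(1, 1, 8, 2)),
               class = "domain_error")
})

test_that("attenuation fitting is exact on noiseless exponentials", {
  z <- (0:99) * 0.004
  ft <- fit_attenuation(50 * exp(-1.5 * z), axial_spacing_um = 4)
  expect_equal(ft$mu_per_mm, 1.5, tolerance = 1e-6)
  expect_equal(ft$goodness, 1, tolerance = 1e-9)
  expect_equal(ft$mu_per_mm, ft$mu_loglinear, tolerance = 1e-9)
  # constant profile
  expect_equal(fit_attenuation(rep(7, 20), axial_spacing_um = 4)$mu_per_mm, 0,
               tolerance = 1e-9)
  # scale invariance
  noisy <- 50 * exp(-2 * z) * exp(rnorm(100, 0, 0.05))
  f1 <- fit_attenuation(noisy, axial_spacing_um = 4)
  f2 <- fit_attenuation(1000 * noisy, axial_spacing_um = 4)
  expect_equal(f1$mu_per_mm, f2$mu_per_mm, tolerance = 1e-6)
  expect_error(fit_attenuation(c(1, -1, rep(1, 10)), axial_spacing_um = 4),
               class = "fit_domain_error")
  expect_error(fit_attenuation(rep(1, 5), axial_spacing_um = 4),
               class = "invalid_parameter")
})

test_that("attenuation is recovered from averaged speckled A-scans", {
  stack <- generate_ascan(2, 100, 400, 4, speckle_contrast = 0.3,
                          n_realizations = 200, seed = 5)
  ft <- fit_attenuation(rowMeans(stack), axial_spacing_um = 4)
  expect_lt(abs(ft$mu_per_mm - 2) / 2, 0.05)
})

test_that("first-order statistics match hand-computed values", {
  f <- fos_features(matrix(7, 4, 4))
  expect_equal(unname(f), c(7, 0, 0, 0, 0, 7, 0))
  f2 <- fos_features(c(1, 2, 3, 4))
  expect_equal(f2[["mean"]], 2.5)
  expect_equal(f2[["variance"]], 1.25)  # population variance
  expect_equal(f2[["median"]], 2.5)
  # uniform 0..255 histogram -> 8 bits
  expect_equal(fos_features(matrix(0:255, 16, 16))[["entropy"]], 8)
  # skewness/kurtosis sanity on a known asymmetric sample
  g <- fos_features(c(rep(0, 9), 10))
  expect_gt(g[["skewness"]], 0)
})

test_that("GLCM micro-examples reproduce hand-derived matrices and statistics", {
  q1 <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
  P1 <- compute_glcm(q1, 0, 1, levels = 2)
  expect_equal(unclass(P1), matrix(c(0.5, 0, 0, 0.5), 2, 2), ignore_attr = TRUE)
  s1 <- glcm_features(P1)
  expect_equal(unname(s1), c(0, 0.5, 1, 1, 1), tolerance = 1e-12)
  q2 <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE)
  s2 <- glcm_features(compute_glcm(q2, 0, 1, levels = 2))
  expect_equal(unname(s2), c(1, 0.5, -1, 0.5, 1), tolerance = 1e-12)
  # uniform GLCM closed forms
  L <- 8
  Pu <- matrix(1 / L^2, L, L)
  su <- glcm_features(Pu)
  expect_equal(su[["energy"]], 1 / L^2)
  expect_equal(su[["entropy"]], 2 * log2(L))
  expect_error(glcm_features(Pu * 2), class = "invariant_error")
  expect_error(compute_glcm(q1, 30), class = "invalid_parameter")
  expect_error(compute_glcm(q1, 0, distance = 5), class = "empty_pair")
})

test_that("GLRLM micro-example reproduces hand-derived run statistics", {
  q <- matrix(c(0, 0, 1, 1, 1, 1), 2, 3, byrow = TRUE)
  r <- compute_glrlm(q, 0, levels = 2)
  expect_equal(attr(r, "Nr"), 3)
  expect_equal(attr(r, "Np"), 6)
  s <- glrlm_features(r)
  expect_equal(s[["SRE"]], (1 / 4 + 1 + 1 / 9) / 3, tolerance = 1e-12)
  expect_equal(s[["LRE"]], 14 / 3, tolerance = 1e-12)
  expect_equal(s[["GLN"]], 5 / 3, tolerance = 1e-12)
  expect_equal(s[["RLN"]], 1, tolerance = 1e-12)
  expect_equal(s[["RP"]], 0.5, tolerance = 1e-12)
  expect_equal(s[["LGRE"]], 0.5, tolerance = 1e-12)
  expect_equal(s[["HGRE"]], 3, tolerance = 1e-12)
  # single run of length 4
  r4 <- compute_glrlm(matrix(0L, 1, 4), 0, levels = 1)
  s4 <- glrlm_features(r4)
  expect_equal(unname(s4[c("SRE", "LRE", "RP", "GLN", "RLN")]),
               c(1 / 16, 16, 0.25, 1, 1))
  # checkerboard: all runs length 1 in rows
  cb <- outer(1:4, 1:4, `+`) %% 2
  scb <- glrlm_features(compute_glrlm(cb, 0, levels = 2))
  expect_equal(unname(scb[c("SRE", "LRE", "RP")]), c(1, 1, 1))
})

test_that("GLCM and GLRLM match brute-force enumeration on random images", {
  set.seed(123)
  for (i in 1:25) {
    L <- sample(2:5, 1)
    q <- matrix(sample(0:(L - 1), 64, replace = TRUE), 8, 8)
    for (d in c(0, 45, 90, 135)) {
      expect_equal(unclass(compute_glcm(q, d, 1, levels = L)),
                   brute_glcm(q, d, 1, levels = L), ignore_attr = TRUE)
      mine <- compute_glrlm(q, d, levels = L)
      oracle <- brute_glrlm(q, d, levels = L)
      expect_equal(unclass(mine), oracle, ignore_attr = TRUE)
      expect_equal(glrlm_features(mine), glrlm_stats_oracle(oracle, 64),
                   tolerance = 1e-12)
    }
  }
})

test_that("texture statistics respect their analytic ranges", {
  set.seed(9)
  for (i in 1:10) {
    q <- quantize_gray_levels(matrix(runif(400), 20, 20), 8)
    for (d in c(0, 45, 90, 135)) {
      g <- glcm_features(compute_glcm(q, d, 1, levels = 8))
      expect_true(g[["energy"]] > 0 && g[["energy"]] <= 1)
      expect_true(g[["entropy"]] >= 0 && g[["entropy"]] <= 2 * log2(8))
      expect_true(g[["homogeneity"]] > 0 && g[["homogeneity"]] <= 1)
      expect_true(abs(g[["correlation"]]) <= 1 + 1e-12)
      r <- glrlm_features(compute_glrlm(q, d, levels = 8))
      expect_true(all(r > 0))
      expect_lte(r[["SRE"]], 1)
      expect_gte(r[["LRE"]], 1)
    }
  }
})

test_that("rotating the image by 90 degrees swaps paired directions", {
  set.seed(31)
  q <- matrix(sample(0:7, 144, replace = TRUE), 12, 12)
  qr <- t(q)[, nrow(q):1]  # 90-degree rotation
  for (pair in list(c(0, 90), c(45, 135))) {
    expect_equal(glcm_features(compute_glcm(q, pair[1], levels = 8)),
                 glcm_features(compute_glcm(qr, pair[2], levels = 8)),
                 tolerance = 1e-12)
    expect_equal(glrlm_features(compute_glrlm(q, pair[1], levels = 8)),
                 glrlm_features(compute_glrlm(qr, pair[2], levels = 8)),
                 tolerance = 1e-12)
  }
})

test_that("the assembled feature vector has the fixed 56-name schema", {
  spec <- cohort_specs()$healthy
  g <- generate_bscan(spec)
  r <- roi(160, 150, 48, 48, layer = "dermis")
  v <- assemble_feature_vector(g$bscan, r)
  expect_length(v, 56L)
  expect_true(all(is.finite(v)))
  expect_equal(names(v)[1], "attenuation_mu")
  expect_equal(sum(startsWith(names(v), "fos_")), 7L)
  expect_equal(sum(startsWith(names(v), "glcm_")), 20L)
  expect_equal(sum(startsWith(names(v), "glrlm_")), 28L)
  expect_identical(v, assemble_feature_vector(g$bscan, r))
})

test_that("the attenuation feature recovers a planted homogeneous rate", {
  # wide, tall ROI on a homogeneous mu = 2 medium, as in a 200 x 200 window
  f <- generate_speckle_field(220, 300, 2, contrast = 0.3, seed = 3)
  clean <- 100 * exp(-2 * (0:219) * 0.004)
  b <- bscan(matrix(clean, 220, 300) * f + 0.01, 4, 10)
  v <- assemble_feature_vector(b, roi(6, 26, 200, 250))
  expect_lt(abs(v[["attenuation_mu"]] - 2) / 2, 0.10)
})

test_that("speckle size estimation matches the smoothing-kernel closed form", {
  f <- generate_speckle_field(512, 512, 3, contrast = 0.3, seed = 7)
  ss <- speckle_size(f, axial_spacing_um = 4, lateral_spacing_um = 4)
  expected <- 4 * 3 * sqrt(log(2))
  expect_lt(abs(ss$axial_fwhm_px - expected) / expected, 0.10)
  expect_lt(abs(ss$lateral_fwhm_px - expected) / expected, 0.10)
  # isotropic generator: axial and lateral widths agree
  expect_lt(abs(ss$axial_fwhm_px - ss$lateral_fwhm_px) /
              ss$mean_fwhm_px, 0.10)
  expect_equal(ss$mean_fwhm_um, ss$mean_fwhm_px * 4)
  expect_error(speckle_size(matrix(1, 64, 64)), class = "no_speckle")
  expect_error(speckle_size(matrix(1, 8, 8)), class = "invalid_parameter")
})
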