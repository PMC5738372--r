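#' Average the A-scans of an ROI into a depth profile
#'
#' @param b A [bscan()] in the linear intensity domain.
#' @param r A [roi()] inside `b`.
#' @return A `depth_profile`: list with `intensities` (per-depth mean across
#'   the ROI's columns, length = ROI height) and `axial_spacing_um`.
#' @export
average_ascan_profile <- function(b, r) {
  stopifnot(inherits(b, "bscan"))
  if (b$intensity_domain != "linear")
    stop_dermoct("attenuation profiles require the linear intensity domain",
                 "domain_error")
  px <- roi_pixels(b, r)
  structure(list(intensities = rowMeans(px),
                 axial_spacing_um = b$axial_spacing_um),
            class = "depth_profile")
}

#' Fit the attenuation coefficient of a depth profile
#'
#' Fits `I(z) = A * exp(-mu * z)` (z in mm from the start of the fit range)
#' by Levenberg-Marquardt nonlinear least squares, initialized from the
#' ordinary-least-squares slope of `log I`. On noiseless exponential input
#' the two estimates coincide. If the nonlinear fit fails to converge, the
#' log-linear estimate is returned with a warning and `converged = FALSE`.
#'
#' @param profile A `depth_profile` from [average_ascan_profile()], or a
#'   numeric vector of intensities (then `axial_spacing_um` must be given).
#' @param fit_range Integer `c(start, end)` sample indices (1-based,
#'   inclusive); default the whole profile. At least 8 samples.
#' @param axial_spacing_um Depth spacing when `profile` is a bare vector.
#' @return An `attenuation_fit`: `mu_per_mm`, `amplitude`, `mu_loglinear`,
#'   `fit_range`, `goodness` (R^2), `converged`.
#' @export
fit_attenuation <- function(profile, fit_range = NULL, axial_spacing_um = NULL) {
  if (inherits(profile, "depth_profile")) {
    y_all <- profile$intensities
    dz <- profile$axial_spacing_um
  } else {
    y_all <- as.numeric(profile)
    dz <- axial_spacing_um
    if (is.null(dz)) stop_dermoct("axial_spacing_um required", "invalid_parameter")
  }
  if (is.null(fit_range)) fit_range <- c(1L, length(y_all))
  fit_range <- as.integer(fit_range)
  if (fit_range[1] < 1L || fit_range[2] > length(y_all) ||
      fit_range[2] - fit_range[1] + 1L < 8L)
    stop_dermoct("fit range must contain at least 8 samples inside the profile",
                 "invalid_parameter")
  y <- y_all[fit_range[1]:fit_range[2]]
  if (any(y <= 0))
    stop_dermoct("non-positive intensities in the fit range", "fit_domain_error")
  z <- (seq_along(y) - 1L) * dz / 1000  # mm from range start
  ols <- stats::lm.fit(cbind(1, z), log(y))
  mu0 <- -ols$coefficients[[2]]
  a0 <- exp(ols$coefficients[[1]])
  r2 <- function(fitted) {
    ss_tot <- sum((y - mean(y))^2)
    if (ss_tot == 0) return(1)
    1 - sum((y - fitted)^2) / ss_tot
  }
  loglin_fitted <- a0 * exp(-mu0 * z)
  # exact fit already (incl. constant profiles): skip the nonlinear step
  if (sum((y - loglin_fitted)^2) <= 1e-20 * sum(y^2)) {
    return(structure(list(mu_per_mm = mu0, amplitude = a0, mu_loglinear = mu0,
                          fit_range = fit_range, goodness = r2(loglin_fitted),
                          converged = TRUE),
                     class = "attenuation_fit"))
  }
  nl <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-mu * z),
                      start = list(A = a0, mu = mu0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(nl)) {
    warning("nonlinear attenuation fit did not converge; log-linear estimate returned")
    return(structure(list(mu_per_mm = mu0, amplitude = a0, mu_loglinear = mu0,
                          fit_range = fit_range, goodness = r2(loglin_fitted),
                          converged = FALSE),
                     class = "attenuation_fit"))
  }
  cf <- stats::coef(nl)
  structure(list(mu_per_mm = unname(cf["mu"]), amplitude = unname(cf["A"]),
                 mu_loglinear = mu0, fit_range = fit_range,
                 goodness = r2(stats::fitted(nl)), converged = TRUE),
            class = "attenuation_fit")
}

#' @export
print.attenuation_fit <- function(x, ...) {
  cat(sprintf("attenuation fit: mu = %.4g 1/mm (log-linear %.4g), R^2 = %.4f%s\n",
              x$mu_per_mm, x$mu_loglinear, x$goodness,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' First-order statistics of an ROI
#'
#' Population mean, variance and standard deviation; sample skewness `g1`
#' and excess kurtosis `g2` (both 0 for constant input by convention);
#' median; and Shannon entropy (base 2) of the 256-bin histogram over the
#' value range.
#'
#' @param px Numeric matrix or vector of pixel values (>= 4 values),
#'   normally the 8-bit display-domain ROI.
#' @param entropy_bins Number of histogram bins, default 256.
#' @return Named vector: `mean`, `variance`, `std`, `skewness`, `kurtosis`,
#'   `median`, `entropy`.
#' @export
fos_features <- function(px, entropy_bins = 256L) {
  v <- as.numeric(px)
  if (length(v) < 4L)
    stop_dermoct("at least 4 pixels required", "invalid_parameter")
  n <- length(v)
  m <- mean(v)
  m2 <- mean((v - m)^2)            # population variance
  if (m2 > 0) {
    skew <- mean((v - m)^3) / m2^1.5
    kurt <- mean((v - m)^4) / m2^2 - 3
  } else skew <- kurt <- 0
  rng <- range(v)
  if (rng[2] > rng[1]) {
    bins <- floor((v - rng[1]) / (rng[2] - rng[1] + 1e-9) * entropy_bins)
    p <- tabulate(bins + 1L, nbins = entropy_bins) / n
    p <- p[p > 0]
    ent <- -sum(p * log2(p))
  } else ent <- 0
  c(mean = m, variance = m2, std = sqrt(m2), skewness = skew,
    kurtosis = kurt, median = stats::median(v), entropy = ent)
}

glcm_offsets <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                     `90` = c(-1L, 0L), `135` = c(-1L, -1L))

#' Gray-level co-occurrence matrix
#'
#' Counts ordered pixel pairs `(i, j)` at displacement `d` along direction
#' `theta` (0 deg: (0, d); 45: (-d, d); 90: (-d, 0); 135: (-d, -d)),
#' symmetrized (both orderings counted) and normalized to sum 1.
#'
#' @param q Integer matrix of gray levels in `0 .. L-1`
#'   (see [quantize_gray_levels()]).
#' @param direction One of 0, 45, 90, 135 (degrees).
#' @param distance Pixel displacement d >= 1.
#' @param levels Number of gray levels L; default `max(q) + 1`.
#' @return A `glcm` object: `L x L` probability matrix with attributes
#'   `direction`, `distance`, `levels`, `symmetric`.
#' @export
compute_glcm <- function(q, direction = 0, distance = 1L, levels = NULL) {
  if (!is.matrix(q)) stop_dermoct("quantized image must be a matrix",
                                  "invalid_parameter")
  distance <- check_count(distance, "distance", 1L)
  dir_key <- as.character(direction)
  if (!dir_key %in% names(glcm_offsets))
    stop_dermoct("direction must be one of 0, 45, 90, 135", "invalid_parameter")
  off <- glcm_offsets[[dir_key]] * distance
  L <- if (is.null(levels)) max(q) + 1L else check_count(levels, "levels", 2L)
  h <- nrow(q); w <- ncol(q)
  r1 <- max(1L, 1L - off[1]):min(h, h - off[1])
  c1 <- max(1L, 1L - off[2]):min(w, w - off[2])
  if (length(r1) < 1L || length(c1) < 1L || h - abs(off[1]) < 1L ||
      w - abs(off[2]) < 1L)
    stop_dermoct("displacement exceeds image extent: no pixel pairs",
                 "empty_pair")
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + off[1], c1 + off[2], drop = FALSE]
  counts <- tabulate(as.integer(a) * L + as.integer(b) + 1L, nbins = L * L)
  P <- matrix(counts, nrow = L, byrow = TRUE)  # row = i (first pixel)
  P <- P + t(P)                                # symmetrize
  P <- P / sum(P)
  structure(P, class = c("glcm", "matrix"), direction = direction,
            distance = distance, levels = L, symmetric = TRUE)
}

#' Haralick statistics of a GLCM
#'
#' Contrast `sum (i-j)^2 P`, energy `sum P^2`, entropy `-sum P log2 P`
#' (with `0 log 0 = 0`), homogeneity (inverse difference moment)
#' `sum P / (1 + (i-j)^2)`, and correlation
#' `sum (i - mu_i)(j - mu_j) P / (sigma_i sigma_j)`, defined as 1 when
#' either marginal variance is 0.
#'
#' @param P A normalized GLCM (from [compute_glcm()], or any matrix summing
#'   to 1).
#' @return Named vector: `contrast`, `energy`, `correlation`, `homogeneity`,
#'   `entropy`.
#' @export
glcm_features <- function(P) {
  P <- unclass(P)
  if (abs(sum(P) - 1) > 1e-8 || any(P < 0))
    stop_dermoct("GLCM must be a normalized probability matrix",
                 "invariant_error")
  L <- nrow(P)
  i <- matrix(seq_len(L) - 1L, L, L)
  j <- t(i)
  contrast <- sum((i - j)^2 * P)
  energy <- sum(P^2)
  nz <- P > 0
  entropy <- -sum(P[nz] * log2(P[nz]))
  homogeneity <- sum(P / (1 + (i - j)^2))
  pi_ <- rowSums(P); pj <- colSums(P)
  mu_i <- sum((seq_len(L) - 1L) * pi_); mu_j <- sum((seq_len(L) - 1L) * pj)
  s_i <- sqrt(sum(((seq_len(L) - 1L) - mu_i)^2 * pi_))
  s_j <- sqrt(sum(((seq_len(L) - 1L) - mu_j)^2 * pj))
  correlation <- if (s_i * s_j == 0) 1 else
    sum((i - mu_i) * (j - mu_j) * P) / (s_i * s_j)
  c(contrast = contrast, energy = energy, correlation = correlation,
    homogeneity = homogeneity, entropy = entropy)
}

#' Gray-level run-length matrix
#'
#' Counts maximal runs of equal gray level along every line of the image in
#' the given direction (0 deg: rows, left to right; 90: columns; 45:
#' anti-diagonals, i.e. lines running up-right; 135: main diagonals).
#'
#' @param q Integer matrix of gray levels in `0 .. L-1`.
#' @param direction One of 0, 45, 90, 135 (degrees).
#' @param levels Number of gray levels L; default `max(q) + 1`.
#' @return A `glrlm` object: `L x max_run` count matrix `p(i, j)` (rows =
#'   gray level, 1-based level index; columns = run length), with attributes
#'   `Nr` (total runs), `Np` (total pixels), `direction`.
#' @export
compute_glrlm <- function(q, direction = 0, levels = NULL) {
  if (!is.matrix(q)) stop_dermoct("quantized image must be a matrix",
                                  "invalid_parameter")
  L <- if (is.null(levels)) max(q) + 1L else check_count(levels, "levels", 1L)
  h <- nrow(q); w <- ncol(q)
  lines <- switch(as.character(direction),
    `0` = split(as.integer(t(q)), rep(seq_len(h), each = w)),
    `90` = split(as.integer(q), rep(seq_len(w), each = h)),
    `45` = {
      rr <- matrix(seq_len(h), h, w); cc <- matrix(seq_len(w), h, w, byrow = TRUE)
      key <- rr + cc
      ord <- order(key, cc)  # along each anti-diagonal, increasing column
      split(as.integer(q)[ord], key[ord])
    },
    `135` = {
      rr <- matrix(seq_len(h), h, w); cc <- matrix(seq_len(w), h, w, byrow = TRUE)
      key <- cc - rr
      ord <- order(key, cc)
      split(as.integer(q)[ord], key[ord])
    },
    stop_dermoct("direction must be one of 0, 45, 90, 135", "invalid_parameter"))
  max_run <- max(h, w)
  p <- matrix(0, nrow = L, ncol = max_run)
  for (ln in lines) {
    r <- rle(ln)
    for (k in seq_along(r$lengths))
      p[r$values[k] + 1L, r$lengths[k]] <- p[r$values[k] + 1L, r$lengths[k]] + 1
  }
  keep <- max(which(colSums(p) > 0), 1L)
  p <- p[, seq_len(keep), drop = FALSE]
  structure(p, class = c("glrlm", "matrix"), Nr = sum(p), Np = h * w,
            direction = direction)
}

#' Run-length statistics of a GLRLM
#'
#' With `p(i, j)` the run counts (gray index i starting at 1, run length j),
#' `Nr` total runs and `Np` total pixels: SRE `= (1/Nr) sum p / j^2`, LRE
#' `= (1/Nr) sum p j^2`, GLN `= (1/Nr) sum_i (sum_j p)^2`, RLN
#' `= (1/Nr) sum_j (sum_i p)^2`, RP `= Nr / Np`, LGRE `= (1/Nr) sum p / i^2`,
#' HGRE `= (1/Nr) sum p i^2`.
#'
#' @param p A `glrlm` from [compute_glrlm()].
#' @return Named vector: `SRE`, `LRE`, `GLN`, `RP`, `RLN`, `LGRE`, `HGRE`.
#' @export
glrlm_features <- function(p) {
  Nr <- attr(p, "Nr"); Np <- attr(p, "Np")
  p <- unclass(p)
  if (is.null(Nr)) Nr <- sum(p)
  if (is.null(Np)) Np <- sum(p * matrix(seq_len(ncol(p)), nrow(p), ncol(p),
                                        byrow = TRUE))
  if (Nr < 1) stop_dermoct("empty run-length matrix", "empty_matrix")
  i <- matrix(seq_len(nrow(p)), nrow(p), ncol(p))
  j <- matrix(seq_len(ncol(p)), nrow(p), ncol(p), byrow = TRUE)
  c(SRE = sum(p / j^2) / Nr,
    LRE = sum(p * j^2) / Nr,
    GLN = sum(rowSums(p)^2) / Nr,
    RP = Nr / Np,
    RLN = sum(colSums(p)^2) / Nr,
    LGRE = sum(p / i^2) / Nr,
    HGRE = sum(p * i^2) / Nr)
}

#' Feature-extraction configuration
#'
#' @param levels Gray levels for texture quantization (default 32).
#' @param distance GLCM pixel displacement (default 1).
#' @param fit_start_offset_px Depth samples skipped below the ROI top before
#'   attenuation fitting, to avoid surface/boundary transients (default 5).
#' @param entropy_bins Histogram bins for first-order entropy (default 256).
#' @param use_despeckled Compute texture on a despeckled copy of the ROI
#'   instead of the raw pixels (default FALSE).
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(levels = 32L, distance = 1L,
                           fit_start_offset_px = 5L, entropy_bins = 256L,
                           use_despeckled = FALSE) {
  structure(list(levels = check_count(levels, "levels", 2L),
                 distance = check_count(distance, "distance", 1L),
                 fit_start_offset_px = check_count(fit_start_offset_px,
                                                   "fit_start_offset_px", 0L),
                 entropy_bins = check_count(entropy_bins, "entropy_bins", 2L),
                 use_despeckled = isTRUE(use_despeckled)),
            class = "feature_config")
}

feature_schema <- function() {
  dirs <- c(0, 45, 90, 135)
  c("attenuation_mu",
    paste0("fos_", c("mean", "variance", "std", "skewness", "kurtosis",
                     "median", "entropy")),
    as.vector(t(outer(c("contrast", "energy", "correlation", "homogeneity",
                        "entropy"),
                      dirs, function(s, d) paste0("glcm_", s, "_", d)))),
    as.vector(t(outer(c("SRE", "LRE", "GLN", "RP", "RLN", "LGRE", "HGRE"),
                      dirs, function(s, d) paste0("glrlm_", s, "_", d)))))
}

#' Extract the full 56-value feature bank from one ROI
#'
#' Computes the attenuation coefficient from the averaged A-scan of the ROI
#' (linear domain), the 7 first-order statistics of the log-compressed 8-bit
#' display ROI, 5 GLCM statistics and 7 GLRLM statistics in each of the four
#' directions 0/45/90/135 degrees, in a fixed order:
#' 1 attenuation + 7 FOS + 20 GLCM + 28 GLRLM = 56 named values.
#'
#' @param b A [bscan()] in the linear domain.
#' @param r A [roi()] inside `b`.
#' @param config A [feature_config()].
#' @return Named numeric vector of 56 finite values.
#' @export
assemble_feature_vector <- function(b, r, config = feature_config()) {
  px <- roi_pixels(b, r)
  prof <- average_ascan_profile(b, r)
  start <- min(config$fit_start_offset_px + 1L, r$height_px - 8L)
  fit <- tryCatch(fit_attenuation(prof, fit_range = c(start, r$height_px)),
                  dermoct_error = function(e) stop_dermoct(
                    sprintf("attenuation_mu: %s", conditionMessage(e)),
                    "feature_error"))
  tex_px <- if (config$use_despeckled)
    despeckle(bscan(px, b$axial_spacing_um, b$lateral_spacing_um,
                    b$intensity_domain, id = "roi"))$pixels else px
  disp <- to_display(tex_px)
  fos <- fos_features(disp, config$entropy_bins)
  q <- quantize_gray_levels(disp, config$levels)
  out <- c(attenuation_mu = fit$mu_per_mm, stats::setNames(fos, paste0("fos_", names(fos))))
  for (d in c(0, 45, 90, 135)) {
    g <- glcm_features(compute_glcm(q, d, config$distance, levels = config$levels))
    out <- c(out, stats::setNames(g, paste0("glcm_", names(g), "_", d)))
  }
  for (d in c(0, 45, 90, 135)) {
    g <- glrlm_features(compute_glrlm(q, d, levels = config$levels))
    out <- c(out, stats::setNames(g, paste0("glrlm_", names(g), "_", d)))
  }
  out <- out[feature_schema()]
  if (any(!is.finite(out)))
    stop_dermoct(sprintf("non-finite feature(s): %s",
                         paste(names(out)[!is.finite(out)], collapse = ", ")),
                 "feature_error")
  out
}

#' Speckle grain size from the autocovariance FWHM
#'
#' Computes the mean-subtracted 2-D autocovariance of a homogeneous speckle
#' region (via FFT, normalized to 1 at zero lag) and measures the full width
#' at half maximum of its central axial (depth) and lateral profiles, with
#' linear interpolation between lag samples.
#'
#' @param x Numeric matrix (>= 32 x 32), a homogeneous speckle region.
#' @param axial_spacing_um,lateral_spacing_um Optional spacings; when given,
#'   widths are also reported in um.
#' @return List: `axial_fwhm_px`, `lateral_fwhm_px`, `mean_fwhm_px`, and the
#'   `_um` counterparts when spacings are supplied.
#' @export
speckle_size <- function(x, axial_spacing_um = NULL, lateral_spacing_um = NULL) {
  if (inherits(x, "bscan")) {
    axial_spacing_um <- axial_spacing_um %||% x$axial_spacing_um
    lateral_spacing_um <- lateral_spacing_um %||% x$lateral_spacing_um
    x <- x$pixels
  }
  if (nrow(x) < 32L || ncol(x) < 32L)
    stop_dermoct("speckle region must be at least 32 x 32", "invalid_parameter")
  v <- x - mean(x)
  if (stats::sd(as.numeric(v)) == 0)
    stop_dermoct("zero-variance input: no speckle to measure", "no_speckle")
  f <- stats::fft(v)
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / length(v)
  ac <- ac / ac[1, 1]
  fwhm_1d <- function(prof) {
    # prof[1] = lag 0; use lags up to half the extent
    n <- length(prof) %/% 2L
    p <- prof[seq_len(n)]
    below <- which(p < 0.5)
    if (length(below) == 0L) return(NA_real_)
    k <- below[1]
    if (k == 1L) return(1)  # falls below 0.5 within the first lag
    # linear interpolation between lags k-2 and k-1 (0-based lags)
    half_width <- (k - 2L) + (p[k - 1L] - 0.5) / (p[k - 1L] - p[k])
    2 * half_width
  }
  axial <- fwhm_1d(ac[, 1])
  lateral <- fwhm_1d(ac[1, ])
  out <- list(axial_fwhm_px = axial, lateral_fwhm_px = lateral,
              mean_fwhm_px = mean(c(axial, lateral)))
  if (!is.null(axial_spacing_um)) out$axial_fwhm_um <- axial * axial_spacing_um
  if (!is.null(lateral_spacing_um)) out$lateral_fwhm_um <- lateral * lateral_spacing_um
  if (!is.null(axial_spacing_um) && !is.null(lateral_spacing_um))
    out$mean_fwhm_um <- mean(c(out$axial_fwhm_um, out$lateral_fwhm_um))
  out
}
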