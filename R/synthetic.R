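#' Specification for a synthetic OCT B-scan
#'
#' Collects the geometry, optics and noise parameters of the two-layer skin
#' phantom used by [generate_bscan()]. Defaults emulate a thin-skin site
#' imaged by a dermatological swept-source scanner: a 512 x 600 pixel frame
#' at 4 um axial / 10 um lateral spacing (about 2 mm depth by 6 mm width),
#' an epidermis of 100 um (thin skin runs roughly 70-120 um), and an
#' undulating dermal-epidermal junction (DEJ). Intensity follows a
#' depth-exponential single-scattering decay with layer-wise attenuation
#' rates, multiplied by a unit-mean correlated speckle field. Confocal-gate
#' and sensitivity roll-off terms are deliberately not modeled.
#'
#' @param image_height_px,image_width_px Frame size in pixels (depth x lateral).
#' @param axial_spacing_um,lateral_spacing_um Physical pixel spacing, um.
#' @param surface_row Row index (1-based) of the air-tissue interface.
#' @param epidermis_thickness_um Epidermal thickness in um.
#' @param mu_epidermis_per_mm,mu_dermis_per_mm Layer attenuation rates, 1/mm.
#' @param surface_amplitude_px,boundary_amplitude_px Sinusoidal undulation
#'   amplitudes (pixels) of the surface and the DEJ.
#' @param boundary_period_px Undulation period in columns.
#' @param boundary_phase Undulation phase in radians.
#' @param speckle_corr_px Speckle correlation length (Gaussian smoothing std,
#'   pixels).
#' @param speckle_contrast Speckle contrast, std/mean of the multiplicative
#'   field. 0 disables speckle.
#' @param lesion Optional list with elements `center_rowcol` (length-2,
#'   row/col), `semi_axes_px` (length-2 ellipse semi-axes), `mu_lesion_per_mm`
#'   and optionally `texture_corr_px` (speckle correlation inside the lesion).
#' @param surface_intensity Backscatter amplitude at the surface (arbitrary
#'   linear units).
#' @param noise_floor Additive background intensity.
#' @param seed Integer seed; the generated scan is a deterministic function
#'   of the spec.
#' @return A list of class `synthetic_spec`.
#' @seealso [generate_bscan()], [generate_cohort()]
#' @export
synthetic_spec <- function(image_height_px = 512L, image_width_px = 600L,
                           axial_spacing_um = 4, lateral_spacing_um = 10,
                           surface_row = 40L,
                           epidermis_thickness_um = 100,
                           mu_epidermis_per_mm = 3, mu_dermis_per_mm = 1.5,
                           surface_amplitude_px = 0,
                           boundary_amplitude_px = 10,
                           boundary_period_px = 300,
                           boundary_phase = 0,
                           speckle_corr_px = 2,
                           speckle_contrast = 0.3,
                           lesion = NULL,
                           surface_intensity = 100,
                           noise_floor = 0.5,
                           seed = 1L) {
  spec <- list(
    image_height_px = check_count(image_height_px, "image_height_px", 16L),
    image_width_px = check_count(image_width_px, "image_width_px", 16L),
    axial_spacing_um = check_positive(axial_spacing_um, "axial_spacing_um"),
    lateral_spacing_um = check_positive(lateral_spacing_um, "lateral_spacing_um"),
    surface_row = check_count(surface_row, "surface_row", 1L),
    epidermis_thickness_um = check_positive(epidermis_thickness_um,
                                            "epidermis_thickness_um"),
    mu_epidermis_per_mm = check_positive(mu_epidermis_per_mm, "mu_epidermis_per_mm"),
    mu_dermis_per_mm = check_positive(mu_dermis_per_mm, "mu_dermis_per_mm"),
    surface_amplitude_px = check_nonneg(surface_amplitude_px, "surface_amplitude_px"),
    boundary_amplitude_px = check_nonneg(boundary_amplitude_px, "boundary_amplitude_px"),
    boundary_period_px = check_positive(boundary_period_px, "boundary_period_px"),
    boundary_phase = as.numeric(boundary_phase),
    speckle_corr_px = check_positive(speckle_corr_px, "speckle_corr_px"),
    speckle_contrast = check_nonneg(speckle_contrast, "speckle_contrast"),
    lesion = lesion,
    surface_intensity = check_positive(surface_intensity, "surface_intensity"),
    noise_floor = check_nonneg(noise_floor, "noise_floor"),
    seed = check_count(seed, "seed", 0L)
  )
  epi_px <- round(spec$epidermis_thickness_um / spec$axial_spacing_um)
  max_boundary <- spec$surface_row + spec$surface_amplitude_px + epi_px +
    spec$boundary_amplitude_px
  if (max_boundary >= spec$image_height_px)
    stop_dermoct("epidermis band extends beyond the image bottom", "invalid_parameter")
  if (!is.null(lesion)) {
    if (!all(c("center_rowcol", "semi_axes_px", "mu_lesion_per_mm") %in% names(lesion)))
      stop_dermoct("lesion needs center_rowcol, semi_axes_px, mu_lesion_per_mm",
                   "invalid_parameter")
    ctr <- lesion$center_rowcol; ax <- lesion$semi_axes_px
    if (ctr[1] - ax[1] < 1 || ctr[1] + ax[1] > spec$image_height_px ||
        ctr[2] - ax[2] < 1 || ctr[2] + ax[2] > spec$image_width_px)
      stop_dermoct("lesion ellipse does not fit inside the image", "invalid_parameter")
    if (lesion$mu_lesion_per_mm <= 0)
      stop_dermoct("mu_lesion_per_mm must be positive", "invalid_parameter")
  }
  structure(spec, class = "synthetic_spec")
}

#' Simulate a stack of OCT A-scans with exponential depth decay
#'
#' Forward model for the attenuation-coefficient estimator: the expected
#' depth profile is `surface_intensity * exp(-mu_per_mm * z)` with z in mm,
#' and each realization is multiplied by independent unit-mean speckle noise
#' of the requested contrast (std/mean).
#'
#' @param mu_per_mm Attenuation rate in 1/mm (>= 0).
#' @param surface_intensity Intensity at depth zero.
#' @param depth_px Number of depth samples (>= 8).
#' @param axial_spacing_um Depth sampling interval in um.
#' @param speckle_contrast Speckle contrast; 0 gives the noiseless profile.
#' @param n_realizations Number of independent A-scans to draw.
#' @param seed Integer seed.
#' @return A `depth_px` x `n_realizations` matrix of intensities.
#' @examples
#' a <- generate_ascan(2, 100, 64, 10, speckle_contrast = 0, n_realizations = 1)
#' @export
generate_ascan <- function(mu_per_mm, surface_intensity, depth_px,
                           axial_spacing_um, speckle_contrast = 0,
                           n_realizations = 1L, seed = 1L) {
  check_nonneg(mu_per_mm, "mu_per_mm")
  check_positive(surface_intensity, "surface_intensity")
  depth_px <- check_count(depth_px, "depth_px", 8L)
  check_positive(axial_spacing_um, "axial_spacing_um")
  check_nonneg(speckle_contrast, "speckle_contrast")
  n_realizations <- check_count(n_realizations, "n_realizations", 1L)
  z_mm <- (seq_len(depth_px) - 1L) * axial_spacing_um / 1000
  clean <- surface_intensity * exp(-mu_per_mm * z_mm)
  out <- matrix(clean, nrow = depth_px, ncol = n_realizations)
  if (speckle_contrast > 0) {
    set.seed(seed)
    # unit-mean lognormal multiplicative noise with CV = speckle_contrast
    sdlog <- sqrt(log(1 + speckle_contrast^2))
    noise <- matrix(stats::rlnorm(depth_px * n_realizations,
                                  meanlog = -sdlog^2 / 2, sdlog = sdlog),
                    nrow = depth_px)
    out <- out * noise
  }
  out
}

#' Generate a correlated unit-mean speckle field
#'
#' White Gaussian noise is smoothed with a Gaussian kernel of standard
#' deviation `corr_sigma_px`, exponentiated and normalized to unit sample
#' mean, yielding a positive multiplicative field whose autocovariance has
#' full width at half maximum close to `4 * corr_sigma_px * sqrt(log(2))`.
#'
#' @param height_px,width_px Field size (>= 8).
#' @param corr_sigma_px Correlation length: std of the smoothing kernel.
#' @param contrast Target contrast (std/mean), default 0.3.
#' @param seed Integer seed.
#' @return A `height_px` x `width_px` positive matrix with mean exactly 1.
#' @seealso [speckle_size()]
#' @export
generate_speckle_field <- function(height_px, width_px, corr_sigma_px,
                                   contrast = 0.3, seed = 1L) {
  height_px <- check_count(height_px, "height_px", 8L)
  width_px <- check_count(width_px, "width_px", 8L)
  check_positive(corr_sigma_px, "corr_sigma_px")
  check_nonneg(contrast, "contrast")
  set.seed(seed)
  g <- matrix(stats::rnorm(height_px * width_px), nrow = height_px)
  g <- gauss_smooth2d(g, corr_sigma_px)
  s <- stats::sd(as.numeric(g))
  if (s > 0) g <- g / s
  a <- sqrt(log(1 + contrast^2))
  f <- exp(a * g)
  f / mean(f)
}

#' Synthesize a two-layer skin B-scan with ground truth
#'
#' Builds a per-pixel attenuation map (epidermis above the DEJ, dermis below,
#' optional ellipsoidal lesion override), integrates the single-scattering
#' decay down each column from the tissue surface, multiplies by a correlated
#' speckle field (with a separately correlated field inside the lesion) and
#' adds a background floor. The returned ground truth records exactly the
#' boundary rows at which the attenuation rate switches.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `bscan` (a [bscan()] in the linear intensity
#'   domain) and `truth` (list: `boundary`, `surface_rows`, `lesion_mask`,
#'   `mu_map`, `class_label`).
#' @export
generate_bscan <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) spec <- do.call(synthetic_spec, spec)
  h <- spec$image_height_px; w <- spec$image_width_px
  dz_mm <- spec$axial_spacing_um / 1000
  epi_px <- as.integer(round(spec$epidermis_thickness_um / spec$axial_spacing_um))
  cols <- seq_len(w)
  wave <- sin(2 * pi * (cols - 1) / spec$boundary_period_px + spec$boundary_phase)
  surface_rows <- spec$surface_row + as.integer(round(spec$surface_amplitude_px * wave))
  boundary <- surface_rows + epi_px +
    as.integer(round(spec$boundary_amplitude_px * wave))
  boundary <- pmin(pmax(boundary, 2L), h - 1L)

  row_idx <- matrix(seq_len(h), nrow = h, ncol = w)
  surf_m <- matrix(surface_rows, nrow = h, ncol = w, byrow = TRUE)
  bnd_m <- matrix(boundary, nrow = h, ncol = w, byrow = TRUE)
  mu_map <- matrix(spec$mu_dermis_per_mm, nrow = h, ncol = w)
  mu_map[row_idx < bnd_m] <- spec$mu_epidermis_per_mm
  mu_map[row_idx < surf_m] <- 0

  lesion_mask <- matrix(FALSE, nrow = h, ncol = w)
  if (!is.null(spec$lesion)) {
    ctr <- spec$lesion$center_rowcol; ax <- spec$lesion$semi_axes_px
    col_idx <- matrix(cols, nrow = h, ncol = w, byrow = TRUE)
    lesion_mask <- ((row_idx - ctr[1]) / ax[1])^2 +
      ((col_idx - ctr[2]) / ax[2])^2 <= 1
    lesion_mask <- lesion_mask & row_idx >= surf_m
    mu_map[lesion_mask] <- spec$lesion$mu_lesion_per_mm
  }

  att <- apply(mu_map, 2, cumsum) * dz_mm
  clean <- spec$surface_intensity * exp(-att)
  clean[row_idx < surf_m] <- 0

  img <- clean + spec$noise_floor
  if (spec$speckle_contrast > 0) {
    field <- generate_speckle_field(h, w, spec$speckle_corr_px,
                                    contrast = spec$speckle_contrast,
                                    seed = spec$seed)
    if (!is.null(spec$lesion) && !is.null(spec$lesion$texture_corr_px) &&
        any(lesion_mask)) {
      field2 <- generate_speckle_field(h, w, spec$lesion$texture_corr_px,
                                       contrast = spec$speckle_contrast,
                                       seed = derive_seed(spec$seed, 1L))
      field[lesion_mask] <- field2[lesion_mask]
    }
    img <- img * field
  }

  b <- bscan(img, axial_spacing_um = spec$axial_spacing_um,
             lateral_spacing_um = spec$lateral_spacing_um,
             intensity_domain = "linear",
             id = sprintf("synthetic-%d", spec$seed))
  truth <- list(boundary = boundary, surface_rows = surface_rows,
                lesion_mask = lesion_mask, mu_map = mu_map,
                class_label = if (is.null(spec$lesion)) "healthy" else "lesion")
  list(bscan = b, truth = truth)
}

#' Generate a balanced labeled cohort of synthetic B-scans
#'
#' Draws `n_per_class` healthy and `n_per_class` lesion scans. Each item gets
#' a seed derived deterministically from the master seed and a random
#' undulation phase, so speckle realization and boundary geometry vary across
#' the cohort while layer optics stay at the spec values.
#'
#' @param spec_healthy,spec_lesion [synthetic_spec()] objects for the two
#'   classes (`spec_lesion` normally carries a `lesion`).
#' @param n_per_class Scans per class (>= 1).
#' @param seed Master integer seed.
#' @return A list of `2 * n_per_class` elements as returned by
#'   [generate_bscan()], healthy items first.
#' @export
generate_cohort <- function(spec_healthy, spec_lesion, n_per_class, seed = 1L) {
  n_per_class <- check_count(n_per_class, "n_per_class", 1L)
  seed <- check_count(seed, "seed", 0L)
  set.seed(seed)
  phases <- stats::runif(2L * n_per_class, 0, 2 * pi)
  out <- vector("list", 2L * n_per_class)
  for (i in seq_len(2L * n_per_class)) {
    spec <- if (i <= n_per_class) spec_healthy else spec_lesion
    spec$seed <- derive_seed(seed, i + 1L)
    spec$boundary_phase <- phases[i]
    out[[i]] <- generate_bscan(spec)
  }
  out
}
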