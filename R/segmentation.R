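#' Per-pixel local attenuation (log-slope) map
#'
#' At each pixel, fits the slope of the column's log-intensity over a
#' centered depth window and converts it to 1/mm using the axial spacing.
#' Because a least-squares slope over a fixed window is a linear filter,
#' the map is computed by convolving each column of the log image with the
#' slope kernel. Borders are padded by edge replication. On a noiseless
#' exponential column `exp(-mu z)` the interior of the map equals `-mu`.
#'
#' @param b A [bscan()] in the linear intensity domain.
#' @param window_px Odd window length >= 5 and <= image height.
#' @return Numeric matrix of local slopes (1/mm); negative in decaying
#'   tissue.
#' @export
local_attenuation_map <- function(b, window_px = 15L) {
  stopifnot(inherits(b, "bscan"))
  window_px <- check_count(window_px, "window_px", 5L)
  if (window_px %% 2L == 0L)
    stop_dermoct("window_px must be odd", "invalid_parameter")
  h <- nrow(b$pixels)
  if (window_px > h)
    stop_dermoct("window_px exceeds image height", "invalid_parameter")
  half <- window_px %/% 2L
  logi <- log(pmax(b$pixels, 1e-12))
  # edge-replicate pad along depth
  padded <- rbind(logi[rep(1L, half), , drop = FALSE], logi,
                  logi[rep(h, half), , drop = FALSE])
  k <- seq(-half, half)
  w <- k / sum(k^2)  # least-squares slope weights (per px step)
  # filter() convolves each column; reverse kernel for convolution order
  sl <- stats::filter(padded, rev(w), method = "convolution", sides = 2)
  sl <- matrix(as.numeric(sl), nrow = nrow(padded))[(half + 1L):(half + h), ,
                                                    drop = FALSE]
  sl / (b$axial_spacing_um / 1000)
}

#' Detect the dermal-epidermal junction as a minimum-cost path
#'
#' Converts boundary detection to a shortest-path problem: per-column node
#' costs are `1 - ` the normalized magnitude of the vertical gradient of the
#' cost source (typically the [local_attenuation_map()], which steps at the
#' DEJ where the attenuation rate changes). A least-cost-first search over
#' the left-to-right column graph — a virtual source feeding every row of the
#' first column, moves `(c -> c+1, |delta row| <= r_max)`, and a virtual sink
#' collecting the last column — returns the global minimum-cost row trace.
#' On this directed acyclic graph the search is realized as exact
#' column-by-column dynamic programming, which visits nodes in the same
#' least-cost order.
#'
#' @param cost_source A [bscan()] or a numeric matrix such as an attenuation
#'   map.
#' @param r_max Maximum row step between adjacent columns (>= 1), default 2.
#' @param row_range Optional `c(min_row, max_row)` restricting the search
#'   band (e.g. below the tissue surface).
#' @param lateral_smooth_cols Odd width of lateral cost smoothing, default 7.
#' @return A `layer_boundary`: list with `rows` (per-column row indices),
#'   `confidence` (1 - mean path cost, in `[0, 1]`) and `r_max`.
#' @export
detect_dej <- function(cost_source, r_max = 2L, row_range = NULL,
                       lateral_smooth_cols = 7L) {
  m <- if (inherits(cost_source, "bscan")) cost_source$pixels else cost_source
  if (!is.matrix(m) || ncol(m) < 8L)
    stop_dermoct("cost source must be a matrix with >= 8 columns",
                 "invalid_parameter")
  r_max <- check_count(r_max, "r_max", 1L)
  h <- nrow(m); w <- ncol(m)
  # vertical gradient (central differences, one-sided at edges)
  g <- m
  g[2:(h - 1), ] <- (m[3:h, ] - m[1:(h - 2), ]) / 2
  g[1, ] <- m[2, ] - m[1, ]
  g[h, ] <- m[h, ] - m[h - 1, ]
  g <- abs(g)
  if (lateral_smooth_cols > 1L) g <- smooth_rows(g, as.integer(lateral_smooth_cols))
  offset <- 0L
  if (!is.null(row_range)) {
    lo <- max(1L, as.integer(row_range[1])); hi <- min(h, as.integer(row_range[2]))
    if (hi - lo + 1L < 3L)
      stop_dermoct("row_range too narrow", "invalid_parameter")
    g <- g[lo:hi, , drop = FALSE]
    offset <- lo - 1L
    h <- nrow(g)
  }
  rng <- range(g)
  if (rng[2] - rng[1] <= 1e-12)
    stop_dermoct("no boundary contrast: cost source has no gradient structure",
                 "no_boundary_contrast")
  cost <- 1 - (g - rng[1]) / (rng[2] - rng[1])

  # exact DP over the column DAG (uniform-cost search order on a DAG)
  cum <- matrix(Inf, h, w)
  ptr <- matrix(0L, h, w)
  cum[, 1] <- cost[, 1]
  shifts <- seq(-r_max, r_max)
  for (cc in 2:w) {
    prev <- cum[, cc - 1L]
    best <- rep(Inf, h)
    barg <- integer(h)
    for (s in shifts) {
      # predecessor row = r + s must be valid
      idx <- seq_len(h) + s
      ok <- idx >= 1L & idx <= h
      cand <- rep(Inf, h)
      cand[ok] <- prev[idx[ok]]
      upd <- cand < best
      best[upd] <- cand[upd]
      barg[upd] <- idx[upd]
    }
    cum[, cc] <- best + cost[, cc]
    ptr[, cc] <- barg
  }
  rows <- integer(w)
  rows[w] <- which.min(cum[, w])
  for (cc in (w - 1L):1L) rows[cc] <- ptr[rows[cc + 1L], cc + 1L]
  path_cost <- cost[cbind(rows, seq_len(w))]
  structure(list(rows = rows + offset,
                 confidence = max(0, 1 - mean(path_cost)),
                 r_max = r_max,
                 path_cost = sum(path_cost)),
            class = "layer_boundary")
}

#' @export
print.layer_boundary <- function(x, ...) {
  cat(sprintf("DEJ boundary over %d columns, rows %d..%d, confidence %.3f\n",
              length(x$rows), min(x$rows), max(x$rows), x$confidence))
  invisible(x)
}

#' Smooth a layer boundary with a centered moving average
#'
#' Rows are averaged over a centered window (shrinking at the endpoints) and
#' rounded to the nearest integer. The column-to-column step bound of the
#' original search is re-checked; a violation after rounding triggers a
#' warning, not an error.
#'
#' @param boundary A `layer_boundary`.
#' @param window_cols Odd window width >= 1; 1 is the identity.
#' @return A smoothed `layer_boundary`.
#' @export
smooth_boundary <- function(boundary, window_cols = 15L) {
  stopifnot(inherits(boundary, "layer_boundary"))
  window_cols <- check_count(window_cols, "window_cols", 1L)
  if (window_cols %% 2L == 0L)
    stop_dermoct("window_cols must be odd", "invalid_parameter")
  out <- boundary
  out$rows <- as.integer(round(moving_average(boundary$rows, window_cols)))
  if (any(abs(diff(out$rows)) > boundary$r_max))
    warning("smoothed boundary exceeds the step bound r_max after rounding")
  out
}

#' Estimate the tissue surface row
#'
#' The surface is the first row whose lateral-mean intensity exceeds the
#' background by `k` standard deviations, with background statistics taken
#' from the top rows of the frame.
#'
#' @param b A [bscan()].
#' @param k Threshold in background standard deviations, default 3.
#' @param background_rows Number of top rows treated as background, default 8.
#' @return A row index.
#' @export
detect_surface <- function(b, k = 3, background_rows = 8L) {
  prof <- rowMeans(b$pixels)
  bg <- prof[seq_len(min(background_rows, length(prof)))]
  thr <- mean(bg) + k * max(stats::sd(bg), 1e-12)
  # prefer rows that clearly rise above the background level and stay there,
  # so single-row background blips are not mistaken for the surface
  cand <- which(prof > max(thr, 1.2 * mean(bg)))
  if (length(cand) == 0L) cand <- which(prof > thr)
  if (length(cand) == 0L) return(1L)
  n <- length(prof)
  for (i in cand) {
    if (all(prof[i:min(i + 2L, n)] > thr)) return(i)
  }
  cand[1]
}

#' Split a B-scan into layer masks and evenly distributed ROIs
#'
#' The epidermis mask covers rows `surface_row .. boundary - 1` per column and
#' the dermis mask the rows from the boundary to the image bottom; together
#' they partition everything below the surface. Per layer, `n_rois` ROIs are
#' centered laterally at columns `floor((k - 0.5) * W / n_rois) + 1`
#' (k = 1..n) and vertically at the middle of the layer band at that column.
#' Where the band is thinner than `roi_height_px` the ROI height shrinks with
#' a warning; a band thinner than 4 px at an ROI column is an error.
#'
#' @param b A [bscan()].
#' @param boundary A `layer_boundary` for `b`.
#' @param surface_row Surface row index (scalar), see [detect_surface()].
#' @param n_rois ROIs per layer.
#' @param roi_height_px,roi_width_px Requested ROI size.
#' @param site,class_label,subject_id Metadata copied into each ROI.
#' @return List with `epidermis_mask`, `dermis_mask` (logical matrices) and
#'   `rois` (list of [roi()], epidermis first).
#' @export
layer_masks_and_rois <- function(b, boundary, surface_row, n_rois = 10L,
                                 roi_height_px = 64L, roi_width_px = 64L,
                                 site = "unknown", class_label = "healthy",
                                 subject_id = "s0") {
  stopifnot(inherits(b, "bscan"), inherits(boundary, "layer_boundary"))
  h <- nrow(b$pixels); w <- ncol(b$pixels)
  if (length(boundary$rows) != w)
    stop_dermoct("boundary length must equal image width", "invalid_parameter")
  n_rois <- check_count(n_rois, "n_rois", 1L)
  surface_row <- check_count(surface_row, "surface_row", 1L)
  row_idx <- matrix(seq_len(h), h, w)
  bnd <- matrix(boundary$rows, h, w, byrow = TRUE)
  epidermis_mask <- row_idx >= surface_row & row_idx < bnd
  dermis_mask <- row_idx >= surface_row & row_idx >= bnd

  centers <- floor((seq_len(n_rois) - 0.5) * w / n_rois) + 1L
  make_roi <- function(col, top_band, bot_band, layer) {
    band <- bot_band - top_band            # band height (half-open)
    if (band < 4L)
      stop_dermoct(sprintf("%s band thinner than 4 px at column %d", layer, col),
                   "degenerate_layer")
    hgt <- roi_height_px
    if (band < hgt) {
      warning(sprintf("%s band at column %d thinner than roi_height_px; shrunk to %d",
                      layer, col, band))
      hgt <- band
    }
    center <- floor((top_band + bot_band) / 2)
    top <- max(top_band, center - hgt %/% 2L)
    if (top + hgt - 1L >= bot_band) top <- bot_band - hgt
    left <- min(max(1L, col - roi_width_px %/% 2L), w - roi_width_px + 1L)
    roi(top, left, hgt, roi_width_px, layer = layer, site = site,
        class_label = class_label, subject_id = subject_id)
  }
  rois <- c(
    lapply(centers, function(cc) make_roi(cc, surface_row, boundary$rows[cc],
                                          "epidermis")),
    lapply(centers, function(cc) make_roi(cc, boundary$rows[cc], h + 1L,
                                          "dermis")))
  list(epidermis_mask = epidermis_mask, dermis_mask = dermis_mask, rois = rois)
}

#' Segment a B-scan into epidermis and dermis
#'
#' Detects the dermal-epidermal junction by fitting the two-layer
#' attenuation model directly: each A-scan's log intensity (after
#' subtracting the estimated background floor) is piecewise linear with a
#' slope change at the DEJ. The stages are: (1) surface detection and
#' background estimation; (2) an unconstrained two-piece fit to the
#' lateral-mean profile, giving initial layer slopes (i.e. attenuation-rate
#' estimates for epidermis and dermis); (3) per-column localization of the
#' slope changepoint with the layer slopes held fixed — the posterior-mean
#' break under a Gaussian residual model, which is far better conditioned
#' than an unconstrained per-column fit; (4) lateral regularization by a
#' REML-smoothed spline on column-block means (speckle makes neighboring
#' columns' errors correlated, so blocks are averaged first); (5) one
#' refinement pass re-estimating the layer slopes from boundary-excluded
#' bands pooled across all columns. Works on the raw (non-despeckled) scan:
#' the changepoint statistic models the speckle directly, and despeckling
#' would only correlate neighboring A-scans.
#'
#' @param b A [bscan()] in the linear intensity domain.
#' @param despeckle_first Run [despeckle()] before segmenting (default
#'   FALSE; see Details).
#' @param margin_px Candidate breaks are kept this far from the ends of the
#'   usable depth range (default 20).
#' @param block_cols Column-block size for the lateral smoother (default 15).
#' @param basis_dim Spline basis dimension of the lateral smoother
#'   (default 20).
#' @param signal_floor_mult Depth rows are used while the lateral-mean
#'   signal exceeds this multiple of the background floor (default 3).
#' @return List with `boundary` (a `layer_boundary`), `surface_row`,
#'   `mu_epidermis_per_mm` and `mu_dermis_per_mm` (global attenuation-rate
#'   estimates from the refinement pass), and `fit_rows` (the usable depth
#'   range).
#' @export
segment_bscan <- function(b, despeckle_first = FALSE, margin_px = 20L,
                          block_cols = 15L, basis_dim = 20L,
                          signal_floor_mult = 3) {
  stopifnot(inherits(b, "bscan"))
  if (despeckle_first) b <- despeckle(b)
  surf <- detect_surface(b)
  iprof <- rowMeans(b$pixels)
  bg <- mean(iprof[seq_len(min(8L, surf))])
  lx <- log(pmax(b$pixels - bg, 0.05 * max(bg, 1e-12)))
  h <- nrow(lx); W <- ncol(lx)
  a0 <- surf + 4L
  above_floor <- which(iprof - bg > signal_floor_mult * bg)
  hmax <- if (length(above_floor)) max(above_floor) else h
  n <- hmax - a0 + 1L
  if (n < 3L * margin_px)
    stop_dermoct("usable depth range too shallow for boundary detection",
                 "degenerate_layer")
  x <- seq_len(n)
  cand <- (margin_px + 1L):(n - margin_px)
  dz_mm <- b$axial_spacing_um / 1000

  # stage 2: initial slopes from a two-piece fit of the lateral-mean profile
  y <- rowMeans(lx)[a0:hmax]
  rss_lin <- function(yy, xx) sum(stats::lm.fit(cbind(1, xx), yy)$residuals^2)
  rssv <- vapply(cand, function(r)
    rss_lin(y[1:(r - 1L)], x[1:(r - 1L)]) + rss_lin(y[r:n], x[r:n]), numeric(1))
  r0 <- cand[which.min(rssv)]
  upr <- 1:max(10L, r0 - 45L)
  lwr <- min(n - 10L, r0 + 45L):n
  m_e <- stats::lm.fit(cbind(1, x[upr]), y[upr])$coefficients[[2]]
  m_d <- stats::lm.fit(cbind(1, x[lwr]), y[lwr])$coefficients[[2]]
  if (m_e >= m_d)  # boundary contrast requires faster epidermal decay
    warning("epidermis does not decay faster than dermis; boundary may be unreliable")

  soft_breaks <- function(m_e, m_d) {
    dm <- m_e - m_d
    breaks <- numeric(W)
    depth <- numeric(W)
    for (cc in seq_len(W)) {
      u <- lx[a0:hmax, cc] - m_e * x
      cu <- cumsum(u); cuz <- cumsum(u * x)
      cz <- cumsum(x); cz2 <- cumsum(x^2)
      rr <- cand
      su <- cu[n] - cu[rr]; suz <- cuz[n] - cuz[rr]
      sz <- cz[n] - cz[rr]; sz2 <- cz2[n] - cz2[rr]
      cnt <- n - rr
      S1 <- cu[n] + dm * (sz - rr * cnt)
      S2 <- sum(u^2) + 2 * dm * (suz - rr * su) +
        dm^2 * (sz2 - 2 * rr * sz + rr^2 * cnt)
      rss <- S2 - S1^2 / n
      mn <- min(rss)
      sig2 <- max(mn / n, 1e-12)  # guard for (near-)noiseless scans
      w <- exp(-(rss - mn) / (2 * sig2))
      breaks[cc] <- sum(w * rr) / sum(w)
      depth[cc] <- 1 - mn / max(rss)
    }
    list(rows = breaks + a0 - 1L, valley = depth)
  }
  smooth_blocks <- function(rows) {
    cols <- seq_len(W)
    nb <- max(4L, floor(W / block_cols))
    bi <- rep(seq_len(nb), each = ceiling(W / nb), length.out = W)
    bx <- as.numeric(tapply(cols, bi, mean))
    by <- as.numeric(tapply(rows, bi, mean))
    if (stats::var(by) < 1e-8) return(rep(mean(by), W))
    fit <- tryCatch(
      mgcv::gam(by ~ s(bx, k = min(basis_dim, nb - 1L)), method = "REML"),
      error = function(e) NULL)
    if (is.null(fit)) return(moving_average(rows, block_cols * 2L + 1L))
    as.numeric(mgcv::predict.gam(fit, newdata = data.frame(bx = cols)))
  }
  slope_pooled <- function(rows, gap = 12L) {
    num_e <- den_e <- num_d <- den_d <- 0
    for (cc in seq_len(W)) {
      top <- round(rows[cc]) - gap
      bot <- round(rows[cc]) + gap
      if (top - a0 > 10L) {
        xe <- seq_len(top - a0 + 1L)
        ye <- lx[a0:top, cc]
        num_e <- num_e + sum((xe - mean(xe)) * ye)
        den_e <- den_e + sum((xe - mean(xe))^2)
      }
      if (hmax - bot > 10L) {
        xd <- (bot:hmax) - a0 + 1L
        yd <- lx[bot:hmax, cc]
        num_d <- num_d + sum((xd - mean(xd)) * yd)
        den_d <- den_d + sum((xd - mean(xd))^2)
      }
    }
    c(if (den_e > 0) num_e / den_e else m_e,
      if (den_d > 0) num_d / den_d else m_d)
  }

  pass1 <- soft_breaks(m_e, m_d)
  bnd <- smooth_blocks(pass1$rows)
  sl <- slope_pooled(bnd)
  pass2 <- soft_breaks(sl[1], sl[2])
  rows <- as.integer(round(smooth_blocks(pass2$rows)))
  rows <- pmin(pmax(rows, a0 + margin_px), hmax - margin_px)
  boundary <- structure(list(rows = rows,
                             confidence = mean(pass2$valley),
                             r_max = max(1L, max(abs(diff(rows))))),
                        class = "layer_boundary")
  list(boundary = boundary, surface_row = surf,
       mu_epidermis_per_mm = -sl[1] / dz_mm,
       mu_dermis_per_mm = -sl[2] / dz_mm,
       fit_rows = c(a0, hmax))
}

#' Serialize a boundary to JSON
#' @param boundary A `layer_boundary`.
#' @param path Output JSON path.
#' @param image_id Image identifier recorded alongside the rows.
#' @export
write_boundary <- function(boundary, path, image_id = "bscan") {
  jsonlite::write_json(list(image_id = image_id, rows = boundary$rows,
                            confidence = boundary$confidence,
                            r_max = boundary$r_max),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
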