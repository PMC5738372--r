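# Independent brute-force oracles used to validate the texture matrices and
# the shortest-path search.

offsets_for <- function(direction, d = 1L) {
  switch(as.character(direction),
         `0` = c(0L, d), `45` = c(-d, d), `90` = c(-d, 0L), `135` = c(-d, -d))
}

# GLCM by explicit pixel-pair enumeration (symmetrized, normalized).
brute_glcm <- function(q, direction, d = 1L, levels = max(q) + 1L) {
  off <- offsets_for(direction, d)
  P <- matrix(0, levels, levels)
  for (r in seq_len(nrow(q))) for (cc in seq_len(ncol(q))) {
    r2 <- r + off[1]; c2 <- cc + off[2]
    if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
      i <- q[r, cc] + 1L; j <- q[r2, c2] + 1L
      P[i, j] <- P[i, j] + 1
      P[j, i] <- P[j, i] + 1
    }
  }
  P / sum(P)
}

# GLRLM by walking every line of the image in the given direction and
# counting maximal runs.
brute_glrlm <- function(q, direction, levels = max(q) + 1L) {
  h <- nrow(q); w <- ncol(q)
  lines <- list()
  if (direction == 0) {
    for (r in seq_len(h)) lines[[length(lines) + 1L]] <- q[r, ]
  } else if (direction == 90) {
    for (cc in seq_len(w)) lines[[length(lines) + 1L]] <- q[, cc]
  } else if (direction == 45) {
    for (s in 2:(h + w)) {
      cells <- which(outer(seq_len(h), seq_len(w), `+`) == s, arr.ind = TRUE)
      cells <- cells[order(cells[, 2]), , drop = FALSE]
      lines[[length(lines) + 1L]] <- q[cells]
    }
  } else if (direction == 135) {
    for (s in (1 - h):(w - 1)) {
      cells <- which(outer(seq_len(h), seq_len(w),
                           function(r, cc) cc - r) == s, arr.ind = TRUE)
      cells <- cells[order(cells[, 2]), , drop = FALSE]
      lines[[length(lines) + 1L]] <- q[cells]
    }
  }
  maxrun <- max(h, w)
  p <- matrix(0, levels, maxrun)
  for (ln in lines) {
    k <- 1L
    while (k <= length(ln)) {
      j <- k
      while (j < length(ln) && ln[j + 1L] == ln[k]) j <- j + 1L
      len <- j - k + 1L
      p[ln[k] + 1L, len] <- p[ln[k] + 1L, len] + 1
      k <- j + 1L
    }
  }
  keep <- max(which(colSums(p) > 0), 1L)
  p[, seq_len(keep), drop = FALSE]
}

# The five co-occurrence statistics evaluated by explicit double loops.
glcm_stats_oracle <- function(P) {
  L <- nrow(P)
  contrast <- energy <- entropy <- homog <- 0
  mu_i <- mu_j <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    contrast <- contrast + (i - j)^2 * p
    energy <- energy + p^2
    if (p > 0) entropy <- entropy - p * log2(p)
    homog <- homog + p / (1 + (i - j)^2)
    mu_i <- mu_i + (i - 1) * p
    mu_j <- mu_j + (j - 1) * p
  }
  s_i <- s_j <- corr <- 0
  for (i in 1:L) for (j in 1:L) {
    s_i <- s_i + (i - 1 - mu_i)^2 * P[i, j]
    s_j <- s_j + (j - 1 - mu_j)^2 * P[i, j]
  }
  s_i <- sqrt(s_i); s_j <- sqrt(s_j)
  if (s_i * s_j == 0) corr <- 1 else {
    for (i in 1:L) for (j in 1:L)
      corr <- corr + (i - 1 - mu_i) * (j - 1 - mu_j) * P[i, j] / (s_i * s_j)
  }
  c(contrast = contrast, energy = energy, correlation = corr,
    homogeneity = homog, entropy = entropy)
}

glrlm_stats_oracle <- function(p, Np) {
  Nr <- sum(p)
  i <- matrix(seq_len(nrow(p)), nrow(p), ncol(p))
  j <- matrix(seq_len(ncol(p)), nrow(p), ncol(p), byrow = TRUE)
  c(SRE = sum(p / j^2) / Nr, LRE = sum(p * j^2) / Nr,
    GLN = sum(rowSums(p)^2) / Nr, RP = Nr / Np,
    RLN = sum(colSums(p)^2) / Nr, LGRE = sum(p / i^2) / Nr,
    HGRE = sum(p * i^2) / Nr)
}

# Node-cost transform mirroring detect_dej with lateral smoothing off, and
# exhaustive enumeration of every feasible left-to-right path.
dej_cost_matrix <- function(m) {
  h <- nrow(m)
  g <- m
  g[2:(h - 1), ] <- (m[3:h, ] - m[1:(h - 2), ]) / 2
  g[1, ] <- m[2, ] - m[1, ]
  g[h, ] <- m[h, ] - m[h - 1, ]
  g <- abs(g)
  1 - (g - min(g)) / (max(g) - min(g))
}

enumerate_min_path <- function(cost, r_max = 1L) {
  h <- nrow(cost); w <- ncol(cost)
  best <- Inf
  recurse <- function(col, row, acc) {
    acc <- acc + cost[row, col]
    if (acc >= best) return()
    if (col == w) { best <<- acc; return() }
    for (nr in max(1L, row - r_max):min(h, row + r_max))
      recurse(col + 1L, nr, acc)
  }
  for (r0 in seq_len(h)) recurse(1L, r0, 0)
  best
}

# Small synthetic cohort shared by modeling tests: gaussian feature matrix
# with optional class shift on the first feature.
toy_feature_table <- function(n_per_class = 30L, n_features = 5L, shift = 0,
                              seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per_class
  X <- matrix(rnorm(n * n_features), n, n_features)
  labels <- rep(c("healthy", "lesion"), each = n_per_class)
  X[labels == "lesion", 1] <- X[labels == "lesion", 1] + shift
  colnames(X) <- paste0("f", seq_len(n_features))
  vectors <- lapply(seq_len(n), function(i) stats::setNames(X[i, ], colnames(X)))
  rois <- lapply(seq_len(n), function(i)
    roi(10, 10, 8, 8, layer = "lesion", class_label = labels[i],
        subject_id = sprintf("s%02d", i)))
  feature_table(vectors, rois)
}

# Criterion-level synthetic scan: sinusoidal DEJ at depth ~200 px.
sinusoid_spec <- function(seed, amplitude = 20, period = 300, contrast = 0.2) {
  synthetic_spec(surface_row = 40L, epidermis_thickness_um = 640,
                 mu_epidermis_per_mm = 3, mu_dermis_per_mm = 1.5,
                 boundary_amplitude_px = amplitude, boundary_period_px = period,
                 speckle_contrast = contrast, seed = seed)
}

# Lesion/healthy cohort specs used by classification tests: lesions have
# twice the dermal attenuation and a coarser speckle texture.
cohort_specs <- function(height = 320L, width = 360L) {
  spec_h <- synthetic_spec(image_height_px = height, image_width_px = width,
                           surface_row = 30L, epidermis_thickness_um = 150,
                           mu_epidermis_per_mm = 3, mu_dermis_per_mm = 1.5,
                           boundary_amplitude_px = 6, boundary_period_px = 180,
                           speckle_corr_px = 2, speckle_contrast = 0.3,
                           seed = 1L)
  lesion_args <- unclass(spec_h)
  lesion_args$lesion <- list(center_rowcol = c(180L, round(width / 2)),
                             semi_axes_px = c(45L, 70L),
                             mu_lesion_per_mm = 3,
                             texture_corr_px = 4)
  list(healthy = spec_h, lesion = do.call(synthetic_spec, lesion_args))
}
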