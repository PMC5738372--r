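# Internal helpers shared across modules.

stop_dermoct <- function(msg, class) {
  stop(structure(class = c(class, "dermoct_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop_dermoct(sprintf("'%s' must be a single integer >= %d", name, min),
                 "invalid_parameter")
  as.integer(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_dermoct(sprintf("'%s' must be a single positive number", name),
                 "invalid_parameter")
  as.numeric(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop_dermoct(sprintf("'%s' must be a single non-negative number", name),
                 "invalid_parameter")
  as.numeric(x)
}

# Deterministic child seeds below 2^31 for per-item reproducibility.
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) %% 100000L) * 20011L + 7919L * i) %% 2147483611L
}

# Centered moving average with shrinking windows at the ends.
moving_average <- function(x, window) {
  n <- length(x)
  half <- window %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

# Separable Gaussian smoothing with circular (wrap-around) boundaries so the
# smoothed field is stationary; used by the speckle generator.
gauss_smooth2d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  sm_cols <- function(m) {
    out <- stats::filter(m, k, method = "convolution", sides = 2, circular = TRUE)
    matrix(as.numeric(out), nrow = nrow(m))
  }
  t(sm_cols(t(sm_cols(x))))
}

# Lateral (column-direction) moving-average smoothing of a matrix.
smooth_rows <- function(m, window) {
  if (window <= 1L) return(m)
  k <- rep(1 / window, window)
  out <- stats::filter(t(m), k, method = "convolution", sides = 2, circular = FALSE)
  out <- t(matrix(as.numeric(out), nrow = ncol(m)))
  # shrink windows at lateral borders rather than leaving NAs
  half <- window %/% 2L
  for (j in c(seq_len(half), ncol(m) - seq_len(half) + 1L)) {
    lo <- max(1L, j - half); hi <- min(ncol(m), j + half)
    out[, j] <- rowMeans(m[, lo:hi, drop = FALSE])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
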