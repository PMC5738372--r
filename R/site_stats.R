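#' Per-site means with 95% confidence intervals
#'
#' For each body site, the mean and the t-based 95% confidence interval
#' `mean +/- t(0.975, n-1) * s / sqrt(n)` (s = sample standard deviation).
#'
#' @param values_by_site Named list of numeric vectors, one per site, each
#'   with >= 2 samples.
#' @return data.frame: `site`, `n`, `mean`, `ci_halfwidth`, `ci_lower`,
#'   `ci_upper`.
#' @export
interval_summary <- function(values_by_site) {
  check_sites(values_by_site, min_n = 2L)
  rows <- lapply(names(values_by_site), function(s) {
    v <- values_by_site[[s]]
    n <- length(v)
    half <- stats::qt(0.975, n - 1) * stats::sd(v) / sqrt(n)
    data.frame(site = s, n = n, mean = mean(v), ci_halfwidth = half,
               ci_lower = mean(v) - half, ci_upper = mean(v) + half)
  })
  do.call(rbind, rows)
}

check_sites <- function(values_by_site, min_sites = 1L, min_n = 2L) {
  if (!is.list(values_by_site) || is.null(names(values_by_site)) ||
      any(names(values_by_site) == ""))
    stop_dermoct("values_by_site must be a named list of numeric vectors",
                 "invalid_parameter")
  if (length(values_by_site) < min_sites)
    stop_dermoct(sprintf("at least %d sites required", min_sites),
                 "invalid_parameter")
  small <- vapply(values_by_site, length, integer(1)) < min_n
  if (any(small))
    stop_dermoct(sprintf("site(s) with fewer than %d samples: %s", min_n,
                         paste(names(values_by_site)[small], collapse = ", ")),
                 "insufficient_data")
  invisible(TRUE)
}

#' One-way fixed-effects ANOVA across sites
#'
#' Classical equal-variance one-way ANOVA of a feature across body sites.
#' When the within-group variance is exactly zero but the group means
#' differ, F is infinite and p is reported as 0 with `degenerate = TRUE`.
#'
#' @param values_by_site Named list of numeric vectors (>= 2 sites, each
#'   >= 2 samples).
#' @return List: `F`, `p`, `df_between`, `df_within`, `degenerate`.
#' @export
anova_by_site <- function(values_by_site) {
  check_sites(values_by_site, min_sites = 2L, min_n = 2L)
  v <- unlist(values_by_site, use.names = FALSE)
  g <- factor(rep(names(values_by_site),
                  vapply(values_by_site, length, integer(1))))
  n <- length(v); k <- nlevels(g)
  grand <- mean(v)
  means <- tapply(v, g, mean)
  ns <- tapply(v, g, length)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((v - means[g])^2)
  dfb <- k - 1L; dfw <- n - k
  if (ssw == 0) {
    if (ssb == 0)
      return(list(F = 0, p = 1, df_between = dfb, df_within = dfw,
                  degenerate = FALSE))
    return(list(F = Inf, p = 0, df_between = dfb, df_within = dfw,
                degenerate = TRUE))
  }
  Fstat <- (ssb / dfb) / (ssw / dfw)
  list(F = Fstat, p = stats::pf(Fstat, dfb, dfw, lower.tail = FALSE),
       df_between = dfb, df_within = dfw, degenerate = FALSE)
}

#' Pairwise Welch t-test map across sites
#'
#' Welch (unequal-variance) two-sample t-tests for every unordered pair of
#' sites, arranged as a symmetric p-value matrix with unit diagonal, plus a
#' significance mask at the requested level and the per-site interval
#' summary and one-way ANOVA. Raw p-values are reported; set `adjust` for a
#' multiplicity correction.
#'
#' @param values_by_site Named list of numeric vectors (>= 2 sites).
#' @param feature,layer Labels carried into the result for bookkeeping.
#' @param alpha Significance level for the mask (default 0.05).
#' @param adjust Multiple-testing correction applied to the off-diagonal
#'   p-values: `"none"` (default), `"bonferroni"` or `"BH"`.
#' @return A `site_comparison`: `pvalue_matrix`, `significant` (logical
#'   mask, diagonal FALSE), `summary` (from [interval_summary()]), `anova`,
#'   `flagged` (matrix of degenerate zero-variance comparisons), `feature`,
#'   `layer`, `sites`.
#' @export
pairwise_ttest_map <- function(values_by_site, feature = "feature",
                               layer = "layer", alpha = 0.05,
                               adjust = c("none", "bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  check_sites(values_by_site, min_sites = 2L, min_n = 2L)
  sites <- names(values_by_site)
  k <- length(sites)
  P <- matrix(1, k, k, dimnames = list(sites, sites))
  flagged <- matrix(FALSE, k, k, dimnames = list(sites, sites))
  for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
    x <- values_by_site[[a]]; y <- values_by_site[[b]]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      p <- if (mean(x) == mean(y)) 1 else 0
      flagged[a, b] <- flagged[b, a] <- TRUE
    } else {
      p <- stats::t.test(x, y, var.equal = FALSE)$p.value
    }
    P[a, b] <- P[b, a] <- p
  }
  if (adjust != "none") {
    up <- upper.tri(P)
    P[up] <- stats::p.adjust(P[up], method = adjust)
    P[lower.tri(P)] <- t(P)[lower.tri(P)]
  }
  structure(list(feature = feature, layer = layer, sites = sites,
                 pvalue_matrix = P,
                 significant = P < alpha & !diag(TRUE, k),
                 summary = interval_summary(values_by_site),
                 anova = anova_by_site(values_by_site),
                 flagged = flagged, alpha = alpha, adjust = adjust),
            class = "site_comparison")
}

#' @export
print.site_comparison <- function(x, ...) {
  cat(sprintf("Site comparison of %s (%s): %d sites, ANOVA F = %.3g (p = %.3g)\n",
              x$feature, x$layer, length(x$sites), x$anova$F, x$anova$p))
  cat(sprintf("%d of %d pairs significant at alpha = %g (%s p-values)\n",
              sum(x$significant) / 2, choose(length(x$sites), 2), x$alpha,
              if (x$adjust == "none") "raw" else x$adjust))
  invisible(x)
}

#' Split a feature table into per-site samples of one feature
#'
#' @param table A `feature_table` with a `site` column.
#' @param feature A feature name in the table schema.
#' @param layer Optional layer filter (`"epidermis"`/`"dermis"`).
#' @return Named list of numeric vectors keyed by site.
#' @export
values_by_site <- function(table, feature, layer = NULL) {
  if (!feature %in% attr(table, "feature_names"))
    stop_dermoct(sprintf("unknown feature '%s'", feature), "invalid_parameter")
  df <- as.data.frame(table)
  if (!is.null(layer)) df <- df[df$layer == layer, , drop = FALSE]
  split(df[[feature]], df$site)
}
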