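#' Filter genes by count support
#'
#' A gene is retained iff its mean count is at least 5, its total count at
#' least 10, and it has zero counts in at most 60% of samples (more than 60%
#' zeros triggers exclusion). A gene can fail several rules but is counted
#' once as excluded.
#'
#' @param expr A raw-count [expr_matrix()].
#' @param min_mean Minimum mean count (default 5).
#' @param min_total Minimum total count (default 10).
#' @param max_zero_frac Maximum tolerated zero fraction (default 0.6).
#' @return List with `expr` (filtered [expr_matrix()]) and `report`
#'   (`gene_filter_report`: `n_input`, `n_retained`, `n_excluded`, and
#'   per-rule exclusion counts `low_mean`, `low_total`, `too_many_zeros`).
#' @export
filter_genes <- function(expr, min_mean = 5, min_total = 10, max_zero_frac = 0.6) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (is_normalized(expr)) stop("filter_genes() expects raw integer counts")
  X <- unclass_matrix(expr)
  if (any(X < 0) || any(abs(X - round(X)) > 1e-8)) {
    stop("counts must be non-negative integers")
  }
  mean_ok <- rowMeans(X) >= min_mean
  total_ok <- rowSums(X) >= min_total
  zeros_ok <- rowMeans(X == 0) <= max_zero_frac
  keep <- mean_ok & total_ok & zeros_ok
  report <- structure(list(
    n_input = nrow(X),
    n_retained = sum(keep),
    n_excluded = sum(!keep),
    low_mean = sum(!mean_ok),
    low_total = sum(!total_ok),
    too_many_zeros = sum(!zeros_ok)), class = "gene_filter_report")
  covar <- attr(expr, "gene_covariate")
  list(expr = expr_matrix(X[keep, , drop = FALSE],
                          gene_covariate = if (!is.null(covar)) unname(covar[keep]) else NULL),
       report = report)
}

#' Normalize a filtered count matrix
#'
#' `log_cpm_quantile` (default): log2 counts-per-million with a 0.5 offset,
#' followed by full quantile normalization across samples, so every sample's
#' value distribution is identical (ties resolved by averaging tied ranks).
#' `covariate_quantile`: a covariate-conditional variant that first removes
#' the smoothed dependence of log-scale expression on a per-gene covariate
#' (gene length or GC), estimated by quantile-binned median regression, then
#' applies the same full quantile normalization.
#'
#' @param expr A filtered raw-count [expr_matrix()].
#' @param method `"log_cpm_quantile"` or `"covariate_quantile"`.
#' @param n_bins Number of equal-count covariate bins for
#'   `covariate_quantile` (default 20).
#' @return A normalized [expr_matrix()].
#' @export
normalize_expression <- function(expr,
                                 method = c("log_cpm_quantile", "covariate_quantile"),
                                 n_bins = 20) {
  stopifnot(inherits(expr, "expr_matrix"))
  method <- match.arg(method)
  if (is_normalized(expr)) stop("expression matrix already normalized")
  X <- unclass_matrix(expr)
  lib <- colSums(X)
  # 0.5 offset keeps zero counts finite on the log scale
  y <- log2(sweep(X + 0.5, 2, lib + 1, "/") * 1e6)

  if (method == "covariate_quantile") {
    covar <- attr(expr, "gene_covariate")
    if (is.null(covar)) {
      stop("method = 'covariate_quantile' requires a gene covariate")
    }
    y <- remove_covariate_trend(y, covar, n_bins = n_bins)
  }
  norm <- quantile_normalize(y)
  dimnames(norm) <- dimnames(X)
  expr_matrix(norm, gene_covariate = unname(attr(expr, "gene_covariate")),
              normalized = TRUE)
}

# subtract, per sample, the binned-median trend of expression on the gene
# covariate: medians over equal-count covariate bins, linearly interpolated
# between bin centres, re-centred on the sample's global median
remove_covariate_trend <- function(y, covar, n_bins = 20) {
  n_bins <- max(2L, min(n_bins, floor(nrow(y) / 5)))
  br <- unique(stats::quantile(covar, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(covar, breaks = br, include.lowest = TRUE, labels = FALSE)
  centres <- tapply(covar, bin, stats::median)
  for (s in seq_len(ncol(y))) {
    med_all <- stats::median(y[, s])
    bin_med <- tapply(y[, s], bin, stats::median)
    trend <- interp_extrap(centres, bin_med, covar)
    y[, s] <- y[, s] - (trend - med_all)
  }
  y
}

# piecewise-linear interpolation through (x0, y0), extended past the end
# knots with the slopes of the outermost segments (constant extrapolation
# would leave the steepest part of a trend untouched below the first knot)
interp_extrap <- function(x0, y0, xout) {
  n <- length(x0)
  out <- stats::approx(x0, y0, xout = xout, rule = 2)$y
  if (n >= 2) {
    lo <- xout < x0[1]
    hi <- xout > x0[n]
    s1 <- (y0[2] - y0[1]) / (x0[2] - x0[1])
    s2 <- (y0[n] - y0[n - 1]) / (x0[n] - x0[n - 1])
    out[lo] <- y0[1] + s1 * (xout[lo] - x0[1])
    out[hi] <- y0[n] + s2 * (xout[hi] - x0[n])
  }
  out
}

# full quantile normalization: each sample's values are replaced by the mean
# of the sample quantiles at their rank; ties receive the average of the
# reference values their ranks span
quantile_normalize <- function(y) {
  ref <- rowMeans(apply(y, 2, sort))
  out <- y
  for (s in seq_len(ncol(y))) {
    r <- rank(y[, s], ties.method = "average")
    # non-integer (tied) ranks interpolate between adjacent reference values
    lo <- floor(r); hi <- ceiling(r)
    out[, s] <- (ref[lo] + ref[hi]) / 2
  }
  out
}
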