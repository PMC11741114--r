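#' Filter chemicals by detection frequency
#'
#' Excludes chemicals whose missing fraction (below detection limit or
#' absent) across samples is strictly greater than `max_missing_frac`; a
#' chemical missing in exactly that fraction of samples is retained. The
#' fixed preprocessing order is filter, then impute, then standardize.
#'
#' @param table A [chem_table()].
#' @param max_missing_frac Exclusion threshold on the per-chemical missing
#'   fraction, in (0, 1); default 0.5 ("missing in more than 50% of samples").
#' @return A list with `table` (the filtered [chem_table()]) and `report`, a
#'   `filter_report` list: `n_input`, `n_retained`, `n_excluded`, the
#'   per-chemical `detection_fraction`, and a data frame of `exclusions`
#'   (chemical_id, missing_fraction, reason).
#' @export
filter_chemicals <- function(table, max_missing_frac = 0.5) {
  stopifnot(inherits(table, "chem_table"))
  if (ncol(table) == 0 || nrow(table) == 0) stop("empty chemical table")
  if (!(max_missing_frac > 0 && max_missing_frac < 1)) {
    stop("`max_missing_frac` must lie in (0, 1)")
  }
  missing_frac <- colMeans(is.na(table))
  keep <- missing_frac <= max_missing_frac
  excl <- data.frame(
    chemical_id = chemical_ids(table)[!keep],
    missing_fraction = unname(missing_frac[!keep]),
    reason = sprintf("missing in %.1f%% of samples (> %.0f%%)",
                     100 * missing_frac[!keep], 100 * max_missing_frac),
    stringsAsFactors = FALSE)
  report <- structure(list(
    n_input = ncol(table),
    n_retained = sum(keep),
    n_excluded = sum(!keep),
    detection_fraction = 1 - missing_frac,
    exclusions = excl), class = "filter_report")
  list(table = as_chem_table(table[, keep, drop = FALSE], table),
       report = report)
}

#' Count chemicals by detection ubiquity
#'
#' Summary counts over a detection table: chemicals detected in every
#' sample ("ubiquitous") and chemicals detected in exactly one sample
#' ("exclusive" to a single site).
#'
#' @param table A [chem_table()].
#' @return Named integer vector with elements `detected`, `ubiquitous`,
#'   `exclusive`.
#' @export
detection_summary <- function(table) {
  stopifnot(inherits(table, "chem_table"))
  det <- colSums(!is.na(table))
  c(detected = sum(det >= 1L),
    ubiquitous = sum(det == nrow(table)),
    exclusive = sum(det == 1L))
}

#' Impute missing chemical concentrations by k nearest neighbours
#'
#' For each missing entry, the imputed value is the unweighted mean of that
#' chemical's observed values in the `k` nearest samples. Sample-to-sample
#' distance is the root mean squared difference over co-observed chemicals,
#' computed on columns standardized using observed entries only; neighbours
#' must have the target chemical observed, and distance ties are broken by
#' sample order. Observed entries are never altered.
#'
#' @param table A [chem_table()].
#' @param k Number of neighbours (default 5).
#' @param distance_weighted If `TRUE`, neighbour averaging is weighted by
#'   inverse distance instead of uniform. Default off.
#' @return A [chem_table()] with no missing entries.
#' @export
knn_impute <- function(table, k = 5, distance_weighted = FALSE) {
  stopifnot(inherits(table, "chem_table"))
  if (k < 1 || k != round(k)) stop("`k` must be a positive integer")
  obs <- !is.na(table)
  short <- colSums(obs) < k
  if (any(short)) {
    stop(sprintf(paste0("chemical(s) observed in fewer than k = %d samples: %s; ",
                        "run filter_chemicals() first"),
                 k, paste(chemical_ids(table)[short], collapse = ", ")))
  }
  if (!anyNA(table)) return(table)
  X <- unclass_matrix(table)
  mu <- colMeans(X, na.rm = TRUE)
  sdv <- apply(X, 2, stats::sd, na.rm = TRUE)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")

  n <- nrow(X)
  # pairwise RMS distance over co-observed standardized chemicals
  D <- matrix(Inf, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- obs[i, ] & obs[j, ]
      if (any(shared)) {
        D[i, j] <- D[j, i] <- sqrt(mean((Z[i, shared] - Z[j, shared])^2))
      }
    }
  }
  out <- X
  for (i in seq_len(n)) {
    miss <- which(!obs[i, ])
    for (j in miss) {
      cand <- which(obs[, j])
      ord <- cand[order(D[i, cand], cand)]   # ties by sample order
      nb <- ord[seq_len(k)]
      if (any(!is.finite(D[i, nb]))) {
        stop(sprintf("sample '%s' shares no observed chemicals with enough neighbours",
                     sample_ids(table)[i]))
      }
      if (distance_weighted) {
        w <- 1 / pmax(D[i, nb], .Machine$double.eps)
        out[i, j] <- sum(w * X[nb, j]) / sum(w)
      } else {
        out[i, j] <- mean(X[nb, j])
      }
    }
  }
  as_chem_table(out, table)
}

#' Standardize chemical columns to zero mean and unit variance
#'
#' Uses the sample (n - 1) standard deviation. Requires a complete table;
#' run [knn_impute()] first.
#'
#' @param table A [chem_table()] with no missing values.
#' @return A standardized [chem_table()] (attribute `standardized = TRUE`).
#' @export
standardize_chemicals <- function(table) {
  stopifnot(inherits(table, "chem_table"))
  if (anyNA(table)) {
    stop("missing values present; impute before standardizing (filter -> impute -> standardize)")
  }
  X <- unclass_matrix(table)
  sdv <- apply(X, 2, stats::sd)
  if (any(sdv == 0)) {
    stop(sprintf("constant chemical column(s): %s",
                 paste(chemical_ids(table)[sdv == 0], collapse = ", ")))
  }
  Z <- scale(X, center = TRUE, scale = sdv)
  attr(Z, "scaled:center") <- NULL
  attr(Z, "scaled:scale") <- NULL
  as_chem_table(Z, table, standardized = TRUE)
}

#' Principal component analysis of the chemical fingerprint
#'
#' QC ordination of a standardized chemical table: how similar are the
#' samples' mixture fingerprints.
#'
#' @param table A standardized, complete [chem_table()].
#' @param n_components Number of components to return.
#' @return List with `scores` (samples x components) and
#'   `explained_variance` (fractions, non-increasing, summing to <= 1).
#' @export
pca_qc <- function(table, n_components) {
  stopifnot(inherits(table, "chem_table"))
  if (anyNA(table)) stop("missing values present; impute first")
  X <- unclass_matrix(table)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-10)
  if (n_components > rank) {
    stop(sprintf("n_components = %d exceeds matrix rank %d", n_components, rank))
  }
  ev <- pc$sdev^2
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       explained_variance = ev[seq_len(n_components)] / sum(ev))
}
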