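#' Configuration for the synthetic two-block generator
#'
#' Defines a planted latent-factor model shared by a chemical concentration
#' block and a gene expression count block, emulating a field study in which
#' a small number of pollution gradients drive both the mixture composition
#' across sites and the transcriptomic response of exposed animals. Defaults
#' emulate the study design this package targets: ~30 water samples, a few
#' hundred detected chemicals with left-censoring and missingness, ~10^4
#' genes organised into coexpression modules, and five latent factors.
#'
#' @param n_samples Number of samples (sites).
#' @param n_chemicals Number of chemicals.
#' @param n_genes Number of genes.
#' @param n_factors Number of planted latent factors; must not exceed
#'   `min(n_samples - 1, n_chemicals, n_genes)`.
#' @param chem_sparsity Fraction of chemicals loading on each factor.
#' @param n_modules Number of planted gene coexpression modules.
#' @param module_size_range Length-2 integer vector `(min, max)` of module
#'   sizes; sizes are drawn uniformly. The default range gives a module-size
#'   spread (tens to hundreds of genes, roughly three quarters of genes in
#'   modules) typical of whole-transcriptome coexpression analyses.
#' @param factor_effect Magnitude of nonzero loadings (dimensionless).
#' @param noise_sd_chem Standard deviation of additive Gaussian noise on the
#'   chemical block.
#' @param nb_dispersion Negative-binomial overdispersion of counts
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param missing_rate Completely-at-random missingness fraction applied to
#'   the chemical block, in [0, 1).
#' @param lod_quantile Per-chemical left-censoring point, in [0, 1): the
#'   lowest `lod_quantile` fraction of each chemical's values is recorded as
#'   below the limit of detection and set to missing.
#' @param seed Integer seed; identical configurations produce bit-identical
#'   datasets.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_samples = 30, n_chemicals = 300, n_genes = 10000,
                         n_factors = 5, chem_sparsity = 0.1, n_modules = 22,
                         module_size_range = c(23, 660), factor_effect = 1,
                         noise_sd_chem = 0.5, nb_dispersion = 0.1,
                         missing_rate = 0.1, lod_quantile = 0.1, seed = 1) {
  cfg <- list(n_samples = n_samples, n_chemicals = n_chemicals,
              n_genes = n_genes, n_factors = n_factors,
              chem_sparsity = chem_sparsity, n_modules = n_modules,
              module_size_range = module_size_range,
              factor_effect = factor_effect, noise_sd_chem = noise_sd_chem,
              nb_dispersion = nb_dispersion, missing_rate = missing_rate,
              lod_quantile = lod_quantile, seed = seed)
  check_count <- function(field, minimum = 1) {
    v <- cfg[[field]]
    if (length(v) != 1 || !is.finite(v) || v < minimum || v != round(v)) {
      stop(sprintf("invalid synth_config: `%s` must be an integer >= %d", field, minimum))
    }
  }
  for (f in c("n_samples", "n_chemicals", "n_genes", "n_factors", "n_modules")) check_count(f)
  check_frac <- function(field, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
    v <- cfg[[field]]
    ok <- length(v) == 1 && is.finite(v) &&
      (if (lo_open) v > lo else v >= lo) && (if (hi_open) v < hi else v <= hi)
    if (!ok) stop(sprintf("invalid synth_config: `%s` out of range", field))
  }
  check_frac("chem_sparsity", lo_open = TRUE)
  check_frac("missing_rate", hi_open = TRUE)
  check_frac("lod_quantile", hi_open = TRUE)
  if (length(module_size_range) != 2 || module_size_range[1] < 1 ||
      module_size_range[1] > module_size_range[2]) {
    stop("invalid synth_config: `module_size_range` must be (min, max) with 1 <= min <= max")
  }
  for (f in c("factor_effect", "noise_sd_chem", "nb_dispersion")) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0) {
      stop(sprintf("invalid synth_config: `%s` must be non-negative", f))
    }
  }
  if (n_factors > min(n_samples - 1, n_chemicals, n_genes)) {
    stop("invalid synth_config: `n_factors` exceeds min(n_samples - 1, n_chemicals, n_genes)")
  }
  if (length(seed) != 1 || !is.finite(seed) || seed != round(seed)) {
    stop("invalid synth_config: `seed` must be an integer")
  }
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic two-block dataset with planted latent structure
#'
#' Factor scores are drawn i.i.d. standard normal and orthogonalized across
#' factors so planted components are identifiable. The chemical block is
#' `scores %*% t(chem_loadings)` plus Gaussian noise, then left-censored per
#' chemical at the configured quantile (censored entries set to missing, not
#' substituted) with additional completely-at-random missingness. Gene counts
#' are negative binomial with log-mean equal to a per-gene baseline (drawn
#' log-uniform so the downstream average-count filter removes a nonzero
#' planted fraction) plus `scores %*% t(gene_loadings)`; gene loadings are
#' module-structured, module `m` being driven by factor `((m - 1) %% K) + 1`.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_dataset` with elements `chem`
#'   ([chem_table()]), `expr` (raw-count [expr_matrix()] with a synthetic
#'   gene-length covariate) and `truth` (a `ground_truth` list: factor
#'   scores, block loadings, module assignment, censoring and missingness
#'   masks, and the genes expected to survive the count filter).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_samples; p <- config$n_chemicals; g <- config$n_genes
  K <- config$n_factors

  # orthonormal factor scores, scaled to approx unit per-column variance
  F0 <- matrix(stats::rnorm(n * K), n, K)
  F0 <- scale(F0, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(F0))[, seq_len(K), drop = FALSE]
  scores <- Q * sqrt(n - 1)
  rownames(scores) <- paste0("S", seq_len(n))
  colnames(scores) <- paste0("factor", seq_len(K))

  # sparse chemical loadings: fixed support size per factor
  support_size <- max(1L, round(config$chem_sparsity * p))
  chem_loadings <- matrix(0, p, K,
                          dimnames = list(paste0("C", seq_len(p)), colnames(scores)))
  for (k in seq_len(K)) {
    idx <- sample.int(p, support_size)
    chem_loadings[idx, k] <- config$factor_effect *
      sample(c(-1, 1), support_size, replace = TRUE) *
      stats::runif(support_size, 0.8, 1.2)
  }

  chem_clean <- scores %*% t(chem_loadings)
  chem_vals <- chem_clean +
    matrix(stats::rnorm(n * p, sd = config$noise_sd_chem), n, p)
  dimnames(chem_vals) <- list(rownames(scores), rownames(chem_loadings))

  # per-chemical left-censoring: the lowest round(q * n) values go below LOD
  censored <- matrix(FALSE, n, p, dimnames = dimnames(chem_vals))
  n_cens <- round(config$lod_quantile * n)
  if (n_cens > 0) {
    for (j in seq_len(p)) {
      censored[order(chem_vals[, j])[seq_len(n_cens)], j] <- TRUE
    }
  }
  mcar <- matrix(stats::runif(n * p) < config$missing_rate, n, p,
                 dimnames = dimnames(chem_vals))
  chem_obs <- chem_vals
  chem_obs[censored | mcar] <- NA_real_

  # module-structured gene loadings
  size_choices <- seq(config$module_size_range[1], config$module_size_range[2])
  sizes <- size_choices[sample.int(length(size_choices), config$n_modules,
                                   replace = TRUE)]
  total <- sum(sizes)
  if (total > g) {
    sizes <- pmax(1L, floor(sizes * g / total))
    total <- sum(sizes)
  }
  assignment <- integer(g)
  assignment[seq_len(total)] <- rep(seq_len(config$n_modules), times = sizes)
  gene_ids <- paste0("g", seq_len(g))
  names(assignment) <- gene_ids
  gene_loadings <- matrix(0, g, K,
                          dimnames = list(gene_ids, colnames(scores)))
  # heavy-tailed loading magnitudes: a few hub genes couple tightly to the
  # driving factor while most members couple weakly, giving the hub-and-spoke
  # connectivity (decaying degree distribution) seen in real coexpression data
  for (m in seq_len(config$n_modules)) {
    members <- which(assignment == m)
    k <- ((m - 1L) %% K) + 1L
    gene_loadings[members, k] <- config$factor_effect *
      stats::rlnorm(length(members), meanlog = log(0.6), sdlog = 0.6)
  }

  base_log_mean <- stats::runif(g, log(0.5), log(500))
  log_mu <- matrix(base_log_mean, g, n) + gene_loadings %*% t(scores)
  mu <- exp(log_mu)
  counts <- if (config$nb_dispersion > 0) {
    matrix(stats::rnbinom(g * n, mu = mu, size = 1 / config$nb_dispersion), g, n)
  } else {
    matrix(stats::rpois(g * n, lambda = mu), g, n)
  }
  dimnames(counts) <- list(gene_ids, rownames(scores))
  gene_length <- round(exp(stats::rnorm(g, log(1500), 0.5)))
  names(gene_length) <- gene_ids

  truth <- structure(list(
    factor_scores = scores,
    chem_loadings = chem_loadings,
    gene_loadings = gene_loadings,
    module_assignment = assignment,
    censored_mask = censored,
    missing_mask = censored | mcar,
    base_log_mean = stats::setNames(base_log_mean, gene_ids),
    expected_surviving = gene_ids[rowMeans(exp(matrix(base_log_mean, g, n))) >= 5]
  ), class = "ground_truth")

  structure(list(chem = chem_table(chem_obs),
                 expr = expr_matrix(counts, gene_covariate = gene_length),
                 truth = truth,
                 config = config),
            class = "synth_dataset")
}

#' Write a synthetic dataset to a directory of delimited text files
#'
#' The chemical table and count matrix round-trip losslessly through
#' [read_chem_table()] / [read_expr_matrix()]; the ground truth is written as
#' tabular sidecar files.
#'
#' @param dataset A `synth_dataset` from [generate_dataset()].
#' @param directory Output directory (created if absent).
#' @param sep Field separator.
#' @param missing_token Token for missing chemical entries.
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixture <- function(dataset, directory, sep = "\t", missing_token = "NA") {
  stopifnot(inherits(dataset, "synth_dataset"))
  ok <- dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop(sprintf("cannot create directory '%s'", directory))
  paths <- c(chem = file.path(directory, "chemicals.tsv"),
             counts = file.path(directory, "counts.tsv"),
             covariate = file.path(directory, "gene_covariate.tsv"),
             factor_scores = file.path(directory, "truth_factor_scores.tsv"),
             chem_loadings = file.path(directory, "truth_chem_loadings.tsv"),
             gene_loadings = file.path(directory, "truth_gene_loadings.tsv"),
             modules = file.path(directory, "truth_modules.tsv"),
             masks = file.path(directory, "truth_masks.tsv"))
  write_chem_table(dataset$chem, paths["chem"], sep = sep,
                   missing_token = missing_token)
  write_expr_matrix(dataset$expr, paths["counts"], sep = sep)
  covar <- attr(dataset$expr, "gene_covariate")
  write_tsv(data.frame(gene_id = names(covar), length = unname(covar)),
            paths["covariate"])
  tr <- dataset$truth
  write_tsv(data.frame(sample_id = rownames(tr$factor_scores),
                       tr$factor_scores, check.names = FALSE),
            paths["factor_scores"])
  write_tsv(data.frame(chemical_id = rownames(tr$chem_loadings),
                       tr$chem_loadings, check.names = FALSE),
            paths["chem_loadings"])
  write_tsv(data.frame(gene_id = rownames(tr$gene_loadings),
                       tr$gene_loadings, check.names = FALSE),
            paths["gene_loadings"])
  write_tsv(data.frame(gene_id = names(tr$module_assignment),
                       module_id = unname(tr$module_assignment)),
            paths["modules"])
  idx <- which(tr$missing_mask, arr.ind = TRUE)
  write_tsv(data.frame(sample_id = rownames(tr$missing_mask)[idx[, 1]],
                       chemical_id = colnames(tr$missing_mask)[idx[, 2]],
                       censored = tr$censored_mask[idx]),
            paths["masks"])
  invisible(paths)
}

#' Synthetic stand-in for a 30-site chemical detection survey
#'
#' Constructs a synthetic samples x chemicals concentration table whose
#' per-chemical detection counts reproduce the headline marginals of the
#' field survey this package emulates: `n_detected` chemicals observed at
#' least once across `n_sites` sites, of which `n_ubiquitous` are detected at
#' every site, `n_exclusive` at exactly one site, and `n_prevalent` at enough
#' sites to survive the 50%-missingness detection filter. This is synthetic
#' data for exercising the counting and filtering operations; it carries no
#' real concentrations.
#'
#' @param n_sites Number of sampling sites.
#' @param n_detected Total number of detected chemicals.
#' @param n_prevalent Number detected in at least `ceiling(n_sites / 2)`
#'   sites (the set retained by [filter_chemicals()] at the 0.5 threshold).
#' @param n_ubiquitous Number detected at every site (subset of prevalent).
#' @param n_exclusive Number detected at exactly one site.
#' @param seed Integer seed.
#' @return A [chem_table()] with planted detection counts in attribute
#'   `detection_counts`.
#' @export
synth_chem_survey <- function(n_sites = 30, n_detected = 385,
                              n_prevalent = 215, n_ubiquitous = 90,
                              n_exclusive = 44, seed = 20) {
  stopifnot(n_ubiquitous <= n_prevalent,
            n_prevalent + n_exclusive <= n_detected,
            n_sites >= 4)
  set.seed(seed)
  keep_min <- ceiling(n_sites / 2)       # detected >= keep_min survives the filter
  counts <- c(rep(n_sites, n_ubiquitous),
              sample(seq(keep_min, n_sites - 1), n_prevalent - n_ubiquitous,
                     replace = TRUE),
              sample(seq(2, keep_min - 1), n_detected - n_prevalent - n_exclusive,
                     replace = TRUE),
              rep(1L, n_exclusive))
  vals <- matrix(NA_real_, n_sites, n_detected,
                 dimnames = list(paste0("site", seq_len(n_sites)),
                                 paste0("chem", seq_len(n_detected))))
  for (j in seq_len(n_detected)) {
    sites <- sample.int(n_sites, counts[j])
    vals[sites, j] <- exp(stats::rnorm(counts[j], mean = 0, sd = 1.5))
  }
  out <- chem_table(vals)
  attr(out, "detection_counts") <- counts
  out
}
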