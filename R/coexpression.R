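#' Configuration for the bootstrap-ensemble coexpression network
#'
#' Each ensemble run bootstraps the samples, perturbs the expression values
#' with Gaussian noise, computes Pearson correlations, and thresholds them so
#' the run's network approximates scale-free topology; edges present in at
#' least `consensus_frac` of the runs form the consensus network.
#'
#' @param n_runs Number of ensemble runs (default 50).
#' @param noise_sd Perturbation scale in units of per-gene standard
#'   deviation (default 0.1).
#' @param candidate_thresholds Ascending candidate absolute-correlation
#'   thresholds.
#' @param consensus_frac Fraction of runs an edge must appear in (default 0.5).
#' @param r2_target Scale-free fit quality target for the log-log degree fit
#'   (default 0.8).
#' @param seed Integer seed; run r uses seed `seed + r`.
#' @return A validated list of class `ensemble_config`.
#' @export
ensemble_config <- function(n_runs = 50, noise_sd = 0.1,
                            candidate_thresholds = seq(0.3, 0.9, by = 0.05),
                            consensus_frac = 0.5, r2_target = 0.8, seed = 1) {
  if (n_runs < 1 || n_runs != round(n_runs)) stop("`n_runs` must be a positive integer")
  if (is.unsorted(candidate_thresholds, strictly = TRUE) ||
      any(candidate_thresholds <= 0) || any(candidate_thresholds >= 1)) {
    stop("`candidate_thresholds` must be strictly ascending values in (0, 1)")
  }
  if (!(consensus_frac > 0 && consensus_frac <= 1)) {
    stop("`consensus_frac` must lie in (0, 1]")
  }
  structure(list(n_runs = n_runs, noise_sd = noise_sd,
                 candidate_thresholds = candidate_thresholds,
                 consensus_frac = consensus_frac, r2_target = r2_target,
                 seed = seed),
            class = "ensemble_config")
}

#' Pearson correlations on bootstrapped, noise-perturbed expression
#'
#' Samples are resampled with replacement to the original n, Gaussian noise
#' with standard deviation `noise_sd` times each gene's standard deviation is
#' added, and Pearson correlations are computed over the perturbed resample.
#' Genes with zero variance in a resample get zero correlations (logged in
#' attribute `zero_variance_genes`).
#'
#' @param expr A normalized [expr_matrix()] with at least 4 samples.
#' @param noise_sd Noise scale in per-gene standard-deviation units.
#' @param seed Integer seed.
#' @param resample If `FALSE`, use the identity resample (full data);
#'   intended for validation against the plain Pearson correlation.
#' @return Symmetric gene x gene correlation matrix with unit diagonal.
#' @export
perturbed_bootstrap_correlation <- function(expr, noise_sd = 0.1, seed = 1,
                                            resample = TRUE) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!is_normalized(expr)) stop("expression must be normalized first")
  n <- ncol(expr)
  if (n < 4) stop("need at least 4 samples")
  set.seed(seed)
  idx <- if (resample) sample.int(n, n, replace = TRUE) else seq_len(n)
  X <- t(unclass_matrix(expr))[idx, , drop = FALSE]   # samples x genes
  if (noise_sd > 0) {
    gsd <- apply(X, 2, stats::sd)
    X <- X + matrix(stats::rnorm(length(X)), nrow(X), ncol(X)) *
      rep(noise_sd * gsd, each = nrow(X))
  }
  gsd <- apply(X, 2, stats::sd)
  flat <- gsd == 0
  C <- suppressWarnings(stats::cor(X))
  if (any(flat)) {
    C[flat, ] <- 0
    C[, flat] <- 0
  }
  C[!is.finite(C)] <- 0
  diag(C) <- 1
  C <- (C + t(C)) / 2
  attr(C, "zero_variance_genes") <- colnames(C)[flat]
  C
}

#' Scale-free topology fit of a thresholded correlation network
#'
#' For a given absolute-correlation threshold, builds the graph with edges
#' `|r| >= t`, bins the degrees of non-isolated nodes into log-spaced bins,
#' and fits log10 p(k) against log10 k by least squares. Returns the R^2 and
#' slope of the fit.
#'
#' @param corr_matrix Symmetric correlation matrix.
#' @param threshold Absolute-correlation edge threshold.
#' @param n_bins Number of log-spaced degree bins (default 10).
#' @return List with `r2`, `slope`, `n_edges`, `n_nodes` (non-isolated).
#' @export
scale_free_fit <- function(corr_matrix, threshold, n_bins = 10) {
  A <- abs(corr_matrix) >= threshold
  diag(A) <- FALSE
  k <- rowSums(A)
  k <- k[k > 0]
  if (length(k) < 3 || length(unique(k)) < 3) {
    return(list(r2 = NA_real_, slope = NA_real_, n_edges = sum(A) / 2,
                n_nodes = length(k)))
  }
  br <- unique(exp(seq(log(min(k)), log(max(k)), length.out = n_bins + 1)))
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = nlevels(bin)) / length(k)
  kmid <- tapply(k, bin, mean)
  ok <- freq > 0 & !is.na(kmid)
  if (sum(ok) < 3) {
    return(list(r2 = NA_real_, slope = NA_real_, n_edges = sum(A) / 2,
                n_nodes = length(k)))
  }
  fit <- stats::lm(log10(freq[ok]) ~ log10(kmid[ok]))
  list(r2 = summary(fit)$r.squared, slope = unname(stats::coef(fit)[2]),
       n_edges = sum(A) / 2, n_nodes = length(k))
}

#' Choose the correlation threshold yielding scale-free topology
#'
#' Evaluates each candidate threshold with [scale_free_fit()] and chooses the
#' smallest threshold whose fit attains `r2 >= r2_target` with negative
#' slope; if none qualifies, the threshold maximizing R^2 among
#' negative-slope fits. When no candidate admits a negative-slope fit (e.g.
#' near-uniform degree distributions, where a power-law fit is undefined), a
#' sentinel choice is made with a warning: the flattest available fit, or
#' the largest non-empty threshold if no fit is defined at all. An error is
#' raised only when every candidate graph is empty. The full diagnostic
#' grid is returned.
#'
#' @param corr_matrix Symmetric correlation matrix.
#' @param candidate_thresholds Ascending thresholds in (0, 1).
#' @param r2_target Target R^2 (default 0.8).
#' @param n_bins Degree bins for the log-log fit.
#' @return List with `threshold` (chosen value) and `diagnostics` (data
#'   frame: threshold, r2, slope, n_edges, n_nodes).
#' @export
select_scale_free_threshold <- function(corr_matrix, candidate_thresholds,
                                        r2_target = 0.8, n_bins = 10) {
  diag_rows <- lapply(candidate_thresholds, function(t) {
    f <- scale_free_fit(corr_matrix, t, n_bins = n_bins)
    data.frame(threshold = t, r2 = f$r2, slope = f$slope,
               n_edges = f$n_edges, n_nodes = f$n_nodes)
  })
  dg <- do.call(rbind, diag_rows)
  if (all(dg$n_edges == 0)) stop("all candidate thresholds give an empty graph")
  neg <- !is.na(dg$r2) & !is.na(dg$slope) & dg$slope < 0
  fitted <- !is.na(dg$slope)
  hit <- neg & dg$r2 >= r2_target
  if (any(hit)) {
    chosen <- dg$threshold[which(hit)[1]]
  } else if (any(neg)) {
    chosen <- dg$threshold[which(neg)[which.max(dg$r2[neg])]]
  } else if (any(fitted)) {
    # sentinel: no decaying degree fit among the candidates (e.g. near-
    # uniform degrees); take the candidate closest to a decaying fit
    chosen <- dg$threshold[which(fitted)[which.min(dg$slope[fitted])]]
    warning("no candidate threshold yields a negative-slope degree fit; using flattest available")
  } else {
    # degenerate degree distributions throughout (too few distinct degrees
    # to fit): largest threshold that keeps the graph non-empty
    chosen <- max(dg$threshold[dg$n_edges > 0])
    warning("degree distribution degenerate at every candidate threshold; using largest non-empty")
  }
  list(threshold = chosen, diagnostics = dg)
}

#' Build the consensus coexpression network
#'
#' Runs `n_runs` independent passes of resample, perturb, correlate,
#' scale-free threshold; an edge enters the consensus network iff it is
#' present in at least `consensus_frac` of the runs. Edge support (fraction
#' of runs containing the edge) is recorded for every edge seen at least
#' once.
#'
#' @param expr A normalized [expr_matrix()].
#' @param config An [ensemble_config()].
#' @param run_seeds Optional explicit per-run seeds (length `n_runs`);
#'   defaults to `config$seed + 1:n_runs`. Edge support is invariant to
#'   their order.
#' @return A `consensus_network`: list with `nodes`, `edges` (data frame
#'   gene_a, gene_b, support, in_consensus), `run_thresholds`, `config`.
#' @export
build_consensus_network <- function(expr, config = ensemble_config(),
                                    run_seeds = NULL) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(config, "ensemble_config"))
  if (is.null(run_seeds)) run_seeds <- config$seed + seq_len(config$n_runs)
  if (length(run_seeds) != config$n_runs) {
    stop("`run_seeds` must have length n_runs")
  }
  g <- nrow(expr)
  support <- matrix(0L, g, g)
  thresholds <- numeric(config$n_runs)
  for (r in seq_len(config$n_runs)) {
    C <- perturbed_bootstrap_correlation(expr, noise_sd = config$noise_sd,
                                         seed = run_seeds[r])
    sel <- select_scale_free_threshold(C, config$candidate_thresholds,
                                       r2_target = config$r2_target)
    thresholds[r] <- sel$threshold
    support <- support + (abs(C) >= sel$threshold)
  }
  diag(support) <- 0L
  ut <- upper.tri(support)
  seen <- which(ut & support > 0, arr.ind = TRUE)
  sup <- support[seen] / config$n_runs
  edges <- data.frame(gene_a = rownames(expr)[seen[, 1]],
                      gene_b = rownames(expr)[seen[, 2]],
                      support = sup,
                      in_consensus = sup >= config$consensus_frac,
                      stringsAsFactors = FALSE)
  structure(list(nodes = rownames(expr), edges = edges,
                 run_thresholds = thresholds, config = config),
            class = "consensus_network")
}

#' @export
print.consensus_network <- function(x, ...) {
  cat(sprintf("consensus_network: %d genes, %d consensus edges (%d seen in >= 1 run)\n",
              length(x$nodes), sum(x$edges$in_consensus), nrow(x$edges)))
  invisible(x)
}

#' Detect gene coexpression modules with the map equation (Infomap)
#'
#' Partitions the consensus network into communities using Infomap with edge
#' weights equal to edge support, taking the best of `trials` optimization
#' trials. Communities smaller than `min_module_size` are marked unassigned
#' (NA), as are isolated genes. Module ids are reassigned in order of
#' descending size, module 1 being the largest.
#'
#' @param network A `consensus_network` from [build_consensus_network()].
#' @param min_module_size Minimum genes per reported module (default 10).
#' @param seed Integer seed for the stochastic optimization.
#' @param trials Number of Infomap trials (default 10).
#' @return A `module_partition`: list with `assignment` (named integer
#'   vector over all genes, NA = unassigned) and `sizes` (named, descending).
#' @export
detect_modules <- function(network, min_module_size = 10, seed = 1, trials = 10) {
  stopifnot(inherits(network, "consensus_network"))
  ed <- network$edges[network$edges$in_consensus, , drop = FALSE]
  if (nrow(ed) == 0) stop("consensus network has no edges")
  gr <- igraph::graph_from_data_frame(ed[, c("gene_a", "gene_b")],
                                      directed = FALSE,
                                      vertices = data.frame(name = network$nodes))
  igraph::E(gr)$weight <- ed$support
  set.seed(seed)
  cm <- igraph::cluster_infomap(gr, e.weights = igraph::E(gr)$weight,
                                nb.trials = trials)
  memb <- igraph::membership(cm)
  assignment <- stats::setNames(rep(NA_integer_, length(network$nodes)),
                                network$nodes)
  assignment[names(memb)] <- as.integer(memb)
  # drop singletons created by isolated vertices and undersized communities
  tab <- table(assignment)
  small <- as.integer(names(tab)[tab < min_module_size])
  assignment[assignment %in% small] <- NA_integer_
  kept <- sort(table(assignment), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(kept), names(kept))
  assignment[!is.na(assignment)] <-
    relabel[as.character(assignment[!is.na(assignment)])]
  sizes <- sort(table(assignment), decreasing = TRUE)
  structure(list(assignment = assignment,
                 sizes = stats::setNames(as.integer(sizes), names(sizes))),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d modules over %d genes (%d unassigned)\n",
              length(x$sizes), length(x$assignment), sum(is.na(x$assignment))))
  invisible(x)
}

#' Write a consensus network and partition as delimited text
#'
#' @param network A `consensus_network`.
#' @param partition A `module_partition`.
#' @param directory Output directory.
#' @return Named file paths, invisibly.
#' @export
write_network <- function(network, partition, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(edges = file.path(directory, "network_edges.tsv"),
             modules = file.path(directory, "modules.tsv"),
             thresholds = file.path(directory, "run_thresholds.tsv"))
  write_tsv(network$edges, paths["edges"])
  write_tsv(data.frame(gene_id = names(partition$assignment),
                       module_id = unname(partition$assignment)),
            paths["modules"])
  write_tsv(data.frame(run = seq_along(network$run_thresholds),
                       threshold = network$run_thresholds),
            paths["thresholds"])
  invisible(paths)
}
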