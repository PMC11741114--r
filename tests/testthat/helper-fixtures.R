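# shared fixtures built in code

# strip container classes/attributes down to a plain named matrix
unclass_mat <- function(x) {
  y <- as.matrix(x)
  attributes(y) <- list(dim = dim(x), dimnames = dimnames(x))
  y
}

# small two-block dataset with clear planted structure
small_synth <- function(seed = 1, ...) {
  args <- utils::modifyList(list(
    n_samples = 30, n_chemicals = 40, n_genes = 300, n_factors = 3,
    chem_sparsity = 0.2, n_modules = 3, module_size_range = c(40, 80),
    factor_effect = 1.5, noise_sd_chem = 0.3, nb_dispersion = 0.1,
    missing_rate = 0.05, lod_quantile = 0.05, seed = seed), list(...))
  generate_dataset(do.call(synth_config, args))
}

# genes x samples expression with an exact block correlation structure:
# within-block correlation `rho`, between-block 0 (Gaussian latent model)
block_expr <- function(block_sizes, n_samples, rho = 0.9, seed = 1) {
  set.seed(seed)
  g <- sum(block_sizes)
  lab <- rep(seq_along(block_sizes), block_sizes)
  lat <- matrix(rnorm(length(block_sizes) * n_samples),
                length(block_sizes), n_samples)
  # orthonormal latents so between-block population correlation is exactly 0
  lat <- t(qr.Q(qr(scale(t(lat), scale = FALSE)))) * sqrt(n_samples - 1)
  X <- sqrt(rho) * lat[lab, , drop = FALSE] +
    sqrt(1 - rho) * matrix(rnorm(g * n_samples), g, n_samples)
  rownames(X) <- paste0("g", seq_len(g))
  colnames(X) <- paste0("S", seq_len(n_samples))
  list(expr = expr_matrix(X, normalized = TRUE), labels = lab)
}

# wrap an adjacency matrix as a consensus_network (support 1 on edges)
network_from_adjacency <- function(A, nodes = NULL) {
  if (is.null(nodes)) nodes <- paste0("g", seq_len(nrow(A)))
  idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  structure(list(
    nodes = nodes,
    edges = data.frame(gene_a = nodes[idx[, 1]], gene_b = nodes[idx[, 2]],
                       support = 1, in_consensus = TRUE,
                       stringsAsFactors = FALSE),
    run_thresholds = NA_real_,
    config = ensemble_config(n_runs = 1, consensus_frac = 1)),
    class = "consensus_network")
}

# tiny GMT file on disk; returns its path
write_toy_gmt <- function(sets, path = tempfile(fileext = ".gmt")) {
  write_gmt(sets, path)
  path
}
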