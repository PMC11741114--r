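#' Configuration for sparse generalized canonical correlation analysis
#'
#' @param n_components Number of components (low-dimension representations)
#'   to extract (default 5).
#' @param sparsity Numeric vector, one value per block, each in
#'   `[1/sqrt(p_j), 1]`: the l1 budget of block j is `sparsity[j] * sqrt(p_j)`.
#'   1 means no sparsity. Values are recycled across blocks.
#' @param design Symmetric non-negative block connection matrix C with zero
#'   diagonal; `NULL` (default) connects every pair of blocks with weight 1.
#' @param scheme Objective transform g: `"horst"` (g(x) = x), `"centroid"`
#'   (g(x) = |x|, default), or `"factorial"` (g(x) = x^2).
#' @param max_iter Maximum block-coordinate iterations per component.
#' @param tol Convergence tolerance on the objective gain (default 1e-8).
#' @param scale Scale block columns to unit variance before fitting
#'   (columns are always centered).
#' @param seed Integer seed for the random fallback initialization.
#' @return A list of class `sgcca_config`.
#' @export
sgcca_config <- function(n_components = 5, sparsity = c(0.5, 0.3),
                         design = NULL, scheme = c("centroid", "horst", "factorial"),
                         max_iter = 1000, tol = 1e-8, scale = TRUE, seed = 1) {
  scheme <- match.arg(scheme)
  if (n_components < 1 || n_components != round(n_components)) {
    stop("`n_components` must be a positive integer")
  }
  if (any(sparsity <= 0) || any(sparsity > 1)) {
    stop("`sparsity` values must lie in (0, 1]")
  }
  structure(list(n_components = n_components, sparsity = sparsity,
                 design = design, scheme = scheme, max_iter = max_iter,
                 tol = tol, scale = scale, seed = seed),
            class = "sgcca_config")
}

#' Project a vector onto the intersection of the l2 sphere and an l1 ball
#'
#' Returns `u = S(v, lambda) / ||S(v, lambda)||_2`, where S is
#' soft-thresholding and `lambda >= 0` is the smallest value (found by
#' bisection to tolerance 1e-10) such that `||u||_1 <= l1_budget`. With
#' `l1_budget >= ||v||_1 / ||v||_2` no thresholding occurs; with
#' `l1_budget = 1` the projection selects the single largest-magnitude entry
#' (ties broken by lowest index).
#'
#' @param v Nonzero numeric vector.
#' @param l1_budget l1 budget, at least 1.
#' @return Unit l2-norm vector with `||u||_1 <= l1_budget` (up to bisection
#'   tolerance).
#' @export
project_l1_l2 <- function(v, l1_budget) {
  if (all(v == 0)) stop("cannot project the zero vector")
  if (l1_budget < 1) stop("`l1_budget` must be >= 1")
  u <- v / sqrt(sum(v^2))
  if (sum(abs(u)) <= l1_budget) return(u)
  if (l1_budget == 1) {
    out <- numeric(length(v))
    i <- which.max(abs(v))
    out[i] <- sign(v[i])
    return(out)
  }
  l1_of <- function(lambda) {
    s <- sign(v) * pmax(abs(v) - lambda, 0)
    n2 <- sqrt(sum(s^2))
    if (n2 == 0) return(0)
    sum(abs(s)) / n2
  }
  lo <- 0
  hi <- max(abs(v))
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (l1_of(mid) > l1_budget) lo <- mid else hi <- mid
  }
  s <- sign(v) * pmax(abs(v) - hi, 0)
  s / sqrt(sum(s^2))
}

scheme_g <- function(x, scheme) {
  switch(scheme, horst = x, centroid = abs(x), factorial = x^2)
}
scheme_dg <- function(x, scheme) {
  switch(scheme, horst = rep(1, length(x)), centroid = sign(x), factorial = 2 * x)
}

#' Fit sparse generalized canonical correlation analysis
#'
#' Maximizes `sum_{j<k} C[j,k] * g(cov(X_j a_j, X_k a_k))` over unit-l2-norm,
#' l1-bounded block weight vectors `a_j` by block-coordinate ascent; each
#' update replaces `a_j` with the sparse projection of `X_j' z_j`, where
#' `z_j = sum_k C[j,k] * g'(cov_jk) * X_k a_k` is the inner target. After a
#' component converges, every block is deflated by regressing out its own
#' score, and the next component is fitted on the deflated blocks. The
#' per-sample scores `X_j a_j` are the block low-dimension representations
#' (LDRs); squared weights `a_j^2` sum to 1 per block and component and
#' measure each variable's contribution.
#'
#' @param blocks List of samples x variables numeric matrices (equal row
#'   counts; for the chemical-transcriptome analysis, the standardized
#'   chemical table and the transposed normalized expression matrix).
#'   Columns are centered (and scaled, per config) internally.
#' @param config An [sgcca_config()].
#' @return An `sgcca_fit`: list with `weights` (per block, variables x
#'   components), `scores` (per block, samples x components),
#'   `component_correlation` (for two blocks, Pearson correlation of the
#'   paired scores per component; for J > 2, mean over connected pairs),
#'   `squared_weights`, `objective` (converged value per component),
#'   `objective_trace` (list of per-iteration values), `n_components`,
#'   `convergence` (logical per component), `config`.
#' @export
fit_sgcca <- function(blocks, config = sgcca_config()) {
  stopifnot(is.list(blocks), length(blocks) >= 2,
            inherits(config, "sgcca_config"))
  J <- length(blocks)
  blocks <- lapply(blocks, function(X) {
    X <- as.matrix(X)
    attributes(X) <- list(dim = dim(X), dimnames = dimnames(X))
    X
  })
  n <- unique(vapply(blocks, nrow, 0L))
  if (length(n) != 1) stop("all blocks must have the same number of samples")
  if (is.null(names(blocks))) names(blocks) <- paste0("block", seq_len(J))
  for (j in seq_len(J)) {
    if (is.null(colnames(blocks[[j]]))) {
      colnames(blocks[[j]]) <- paste0(names(blocks)[j], "_v", seq_len(ncol(blocks[[j]])))
    }
  }
  C <- config$design
  if (is.null(C)) { C <- matrix(1, J, J); diag(C) <- 0 }
  if (!isSymmetric(unname(C)) || any(C < 0) || any(diag(C) != 0)) {
    stop("`design` must be symmetric and non-negative with zero diagonal")
  }
  sparsity <- rep_len(config$sparsity, J)
  p <- vapply(blocks, ncol, 0L)
  low <- 1 / sqrt(p)
  if (any(sparsity < low - 1e-12)) {
    stop(sprintf("sparsity below the feasible minimum 1/sqrt(p) for block(s): %s",
                 paste(names(blocks)[sparsity < low - 1e-12], collapse = ", ")))
  }
  budgets <- pmax(sparsity * sqrt(p), 1)

  X <- lapply(blocks, function(B) {
    B <- scale(B, center = TRUE, scale = FALSE)
    if (config$scale) {
      sdv <- apply(B, 2, stats::sd)
      sdv[sdv == 0] <- 1
      B <- sweep(B, 2, sdv, "/")
    }
    B
  })

  pair_idx <- which(upper.tri(C) & C > 0, arr.ind = TRUE)
  objective_of <- function(y) {
    sum(vapply(seq_len(nrow(pair_idx)), function(r) {
      j <- pair_idx[r, 1]; k <- pair_idx[r, 2]
      C[j, k] * scheme_g(stats::cov(y[[j]], y[[k]]), config$scheme)
    }, 0))
  }

  K <- config$n_components
  weights <- lapply(seq_len(J), function(j)
    matrix(NA_real_, p[j], K, dimnames = list(colnames(blocks[[j]]), NULL)))
  scores <- lapply(seq_len(J), function(j)
    matrix(NA_real_, n, K, dimnames = list(rownames(blocks[[j]]), NULL)))
  names(weights) <- names(scores) <- names(blocks)
  comp_cor <- numeric(K)
  objective <- numeric(K)
  traces <- vector("list", K)
  converged <- logical(K)
  set.seed(config$seed)

  k_done <- 0
  for (comp in seq_len(K)) {
    # stop early if some block has been deflated to (numerical) zero
    if (any(vapply(X, function(B) sum(B^2), 0) < 1e-24)) {
      warning(sprintf("block rank exhausted: stopping after %d component(s)", k_done))
      break
    }
    a <- lapply(seq_len(J), function(j) {
      sv <- tryCatch(svd(X[[j]], nu = 0, nv = 1)$v[, 1],
                     error = function(e) NULL)
      if (is.null(sv) || all(sv == 0)) sv <- stats::rnorm(p[j])
      project_l1_l2(sv, budgets[j])
    })
    y <- lapply(seq_len(J), function(j) drop(X[[j]] %*% a[[j]]))
    obj <- objective_of(y)
    trace <- obj
    conv <- FALSE
    for (it in seq_len(config$max_iter)) {
      for (j in seq_len(J)) {
        covs <- vapply(seq_len(J), function(k) {
          if (C[j, k] > 0) stats::cov(y[[j]], y[[k]]) else 0
        }, 0)
        w <- C[j, ] * scheme_dg(covs, config$scheme)
        z <- rowSums(vapply(seq_len(J), function(k) w[k] * y[[k]],
                            numeric(n)))
        grad <- drop(crossprod(X[[j]], z))
        if (all(grad == 0)) next
        a[[j]] <- project_l1_l2(grad, budgets[j])
        y[[j]] <- drop(X[[j]] %*% a[[j]])
      }
      obj_new <- objective_of(y)
      trace <- c(trace, obj_new)
      if (obj_new - obj < config$tol) { conv <- TRUE; obj <- obj_new; break }
      obj <- obj_new
    }
    if (!conv) {
      warning(sprintf("component %d did not converge in %d iterations",
                      comp, config$max_iter))
    }
    # sign convention: largest-magnitude weight entry positive per block
    for (j in seq_len(J)) {
      i <- which.max(abs(a[[j]]))
      if (a[[j]][i] < 0) { a[[j]] <- -a[[j]]; y[[j]] <- -y[[j]] }
      weights[[j]][, comp] <- a[[j]]
      scores[[j]][, comp] <- y[[j]]
    }
    objective[comp] <- obj
    traces[[comp]] <- trace
    converged[comp] <- conv
    pair_cors <- vapply(seq_len(nrow(pair_idx)), function(r) {
      j <- pair_idx[r, 1]; k <- pair_idx[r, 2]
      if (stats::sd(y[[j]]) == 0 || stats::sd(y[[k]]) == 0) return(NA_real_)
      stats::cor(y[[j]], y[[k]])
    }, 0)
    comp_cor[comp] <- mean(pair_cors)
    # projection deflation against each block's own score
    for (j in seq_len(J)) {
      ss <- sum(y[[j]]^2)
      if (ss > 0) {
        X[[j]] <- X[[j]] - y[[j]] %*% (crossprod(y[[j]], X[[j]]) / ss)
      }
    }
    k_done <- comp
  }
  if (k_done == 0) stop("no components could be extracted")
  trim <- function(m) m[, seq_len(k_done), drop = FALSE]
  fit <- structure(list(
    weights = lapply(weights, trim),
    scores = lapply(scores, trim),
    component_correlation = comp_cor[seq_len(k_done)],
    objective = objective[seq_len(k_done)],
    objective_trace = traces[seq_len(k_done)],
    n_components = k_done,
    convergence = converged[seq_len(k_done)],
    config = config), class = "sgcca_fit")
  fit$squared_weights <- squared_weights(fit)
  fit
}

#' @export
print.sgcca_fit <- function(x, ...) {
  cat(sprintf("sgcca_fit: %d blocks (%s), %d component(s)\n",
              length(x$weights), paste(names(x$weights), collapse = ", "),
              x$n_components))
  cat("component correlations:",
      paste(sprintf("%.3f", x$component_correlation), collapse = ", "), "\n")
  invisible(x)
}

#' Squared-weight contributions per variable
#'
#' The squared entries of each unit-l2-norm block weight vector; each
#' variable's share of its block's contribution to a component (LDR). Sums
#' to 1 per block and component; unselected (zero-weight) variables have
#' squared weight 0.
#'
#' @param fit An `sgcca_fit`.
#' @return Per block, a variables x components matrix of squared weights.
#' @export
squared_weights <- function(fit) {
  stopifnot(inherits(fit, "sgcca_fit"))
  lapply(fit$weights, function(W) W^2)
}

#' Variables contributing to a component above a squared-weight cutoff
#'
#' @param fit An `sgcca_fit`.
#' @param block Block name or index.
#' @param component Component index.
#' @param sw_cutoff Squared-weight cutoff (default 0.01).
#' @return Data frame (variable, sw) sorted by descending squared weight.
#' @export
sw_contributors <- function(fit, block = 1, component = 1, sw_cutoff = 0.01) {
  sw <- squared_weights(fit)[[block]][, component]
  sel <- sw > sw_cutoff
  out <- data.frame(variable = names(sw)[sel], sw = unname(sw[sel]),
                    stringsAsFactors = FALSE)
  out[order(-out$sw), , drop = FALSE]
}

#' Fraction of gene-block variance explained by chemical-side scores
#'
#' Orthogonalizes the chemical-side component scores in order, then computes
#' for each component the summed R^2 of every (centered) gene regressed on
#' that score, as a fraction of total gene-block variance. The cumulative
#' fraction equals the R^2 of the gene block regressed jointly on all scores.
#'
#' @param fit An `sgcca_fit` (used for its component count).
#' @param gene_block Samples x genes numeric matrix (centered internally).
#' @param chem_scores Samples x components score matrix; defaults to the
#'   first block's scores in `fit`.
#' @return List with `per_component` and `cumulative` fractions.
#' @export
variance_explained <- function(fit, gene_block, chem_scores = NULL) {
  stopifnot(inherits(fit, "sgcca_fit"))
  if (is.null(chem_scores)) chem_scores <- fit$scores[[1]]
  G <- scale(as.matrix(gene_block), center = TRUE, scale = FALSE)
  zero_var <- apply(G, 2, function(x) all(x == 0))
  if (any(zero_var)) {
    warning(sprintf("%d zero-variance gene column(s) excluded", sum(zero_var)))
    G <- G[, !zero_var, drop = FALSE]
  }
  S <- scale(as.matrix(chem_scores), center = TRUE, scale = FALSE)
  qrS <- qr(S)
  r <- qrS$rank
  Q <- qr.Q(qrS)[, seq_len(r), drop = FALSE]
  total_ss <- sum(G^2)
  per_comp <- vapply(seq_len(ncol(S)), function(k) {
    if (k > r) return(0)
    sum(drop(crossprod(Q[, k], G))^2) / total_ss
  }, 0)
  list(per_component = per_comp, cumulative = cumsum(per_comp))
}

#' Serialize an SGCCA fit to a directory of TSV files
#'
#' @param fit An `sgcca_fit`.
#' @param directory Output directory.
#' @return Named file paths, invisibly.
#' @export
write_sgcca_fit <- function(fit, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (b in names(fit$weights)) {
    pw <- file.path(directory, sprintf("weights_%s.tsv", b))
    ps <- file.path(directory, sprintf("scores_%s.tsv", b))
    psw <- file.path(directory, sprintf("squared_weights_%s.tsv", b))
    W <- fit$weights[[b]]; colnames(W) <- paste0("LDR", seq_len(ncol(W)))
    write_tsv(data.frame(variable = rownames(W), W, check.names = FALSE), pw)
    S <- fit$scores[[b]]; colnames(S) <- paste0("LDR", seq_len(ncol(S)))
    write_tsv(data.frame(sample_id = rownames(S), S, check.names = FALSE), ps)
    SW <- fit$squared_weights[[b]]; colnames(SW) <- paste0("LDR", seq_len(ncol(SW)))
    write_tsv(data.frame(variable = rownames(SW), SW, check.names = FALSE), psw)
    paths <- c(paths, pw, ps, psw)
  }
  pc <- file.path(directory, "components.tsv")
  write_tsv(data.frame(component = seq_len(fit$n_components),
                       correlation = fit$component_correlation,
                       objective = fit$objective,
                       converged = fit$convergence), pc)
  meta <- file.path(directory, "run_metadata.tsv")
  cfg <- fit$config
  write_tsv(data.frame(
    key = c("n_components", "sparsity", "scheme", "max_iter", "tol", "scale", "seed"),
    value = c(cfg$n_components, paste(cfg$sparsity, collapse = ","), cfg$scheme,
              cfg$max_iter, format(cfg$tol), cfg$scale, cfg$seed)), meta)
  invisible(c(paths, components = pc, metadata = meta))
}
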