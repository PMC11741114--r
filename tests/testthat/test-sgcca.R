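test_that("sparse projection reduces to normalization when the budget is loose", {
  v <- c(3, -1, 2, 0.5)
  u <- project_l1_l2(v, sqrt(length(v)))
  expect_equal(u, v / sqrt(sum(v^2)), tolerance = 1e-12)
})

test_that("budget 1 selects the single largest-magnitude entry, ties by lowest index", {
  expect_equal(project_l1_l2(c(1, -4, 2), 1), c(0, -1, 0))
  expect_equal(project_l1_l2(c(3, 3, 1), 1), c(1, 0, 0))
})

test_that("sparse projection matches a dense lambda grid search", {
  v <- c(3, 2, 1)
  u <- project_l1_l2(v, 1.3)
  # oracle: scan lambda over a 1e6-point grid, take the smallest lambda
  # whose normalized soft-threshold meets the budget
  lam <- seq(0, max(abs(v)), length.out = 1e6)
  best <- NULL
  for (l in lam) {
    s <- sign(v) * pmax(abs(v) - l, 0)
    n2 <- sqrt(sum(s^2))
    if (n2 > 0 && sum(abs(s)) / n2 <= 1.3) { best <- s / n2; break }
  }
  expect_equal(u, best, tolerance = 1e-5)
})

test_that("projected vectors satisfy both norm constraints", {
  set.seed(40)
  for (i in 1:25) {
    p <- sample(3:12, 1)
    v <- rnorm(p)
    budget <- runif(1, 1, sqrt(p))
    u <- project_l1_l2(v, budget)
    expect_equal(sum(u^2), 1, tolerance = 1e-10)
    expect_lte(sum(abs(u)), budget + 1e-8)
  }
  expect_error(project_l1_l2(c(0, 0), 1), "zero")
})

test_that("two identical one-variable blocks give correlation 1 and unit weights", {
  set.seed(41)
  x <- matrix(rnorm(12), 12, 1)
  fit <- fit_sgcca(list(a = x, b = x),
                   sgcca_config(n_components = 1, sparsity = c(1, 1), seed = 1))
  expect_equal(fit$component_correlation[1], 1, tolerance = 1e-12)
  expect_equal(unname(fit$weights$a[, 1]), 1)
  expect_equal(unname(fit$weights$b[, 1]), 1)
})

test_that("squared weights sum to one per block and component and flag selection", {
  ds <- small_synth(seed = 42, missing_rate = 0, lod_quantile = 0)
  chem <- standardize_chemicals(ds$chem)
  norm <- normalize_expression(filter_genes(ds$expr)$expr)
  fit <- fit_sgcca(list(chemicals = unclass_mat(chem), genes = t(unclass_mat(norm))),
                   sgcca_config(n_components = 3, sparsity = c(0.5, 0.3), seed = 2))
  for (b in names(fit$squared_weights)) {
    sums <- colSums(fit$squared_weights[[b]])
    expect_equal(unname(sums), rep(1, fit$n_components), tolerance = 1e-10)
    # SW = a^2 exactly, zero iff unselected
    expect_equal(fit$squared_weights[[b]], fit$weights[[b]]^2)
  }
  # forced arithmetic on a known weight vector
  w <- c(0.6, 0.8, 0)
  expect_equal(w^2, c(0.36, 0.64, 0))
  # the contributor selector equals a direct threshold recomputation
  sw1 <- fit$squared_weights$chemicals[, 1]
  direct <- sort(names(sw1)[sw1 > 0.01])
  expect_equal(sort(sw_contributors(fit, "chemicals", 1, 0.01)$variable), direct)
})

test_that("fitted weights satisfy the norm constraints and the objective ascends", {
  ds <- small_synth(seed = 43, missing_rate = 0, lod_quantile = 0)
  chem <- standardize_chemicals(ds$chem)
  norm <- normalize_expression(filter_genes(ds$expr)$expr)
  s <- c(0.6, 0.4)
  fit <- fit_sgcca(list(chemicals = unclass_mat(chem), genes = t(unclass_mat(norm))),
                   sgcca_config(n_components = 2, sparsity = s, seed = 3))
  p <- vapply(fit$weights, nrow, 0L)
  for (j in 1:2) {
    for (k in seq_len(fit$n_components)) {
      a <- fit$weights[[j]][, k]
      expect_equal(sum(a^2), 1, tolerance = 1e-10)
      expect_lte(sum(abs(a)), s[j] * sqrt(p[j]) + 1e-8)
    }
  }
  for (tr in fit$objective_trace) {
    expect_true(all(diff(tr) >= -fit$config$tol))
  }
  # sign convention: largest-magnitude weight entry is positive
  for (j in 1:2) for (k in seq_len(fit$n_components)) {
    a <- fit$weights[[j]][, k]
    expect_gt(a[which.max(abs(a))], 0)
  }
})

test_that("the converged two-variable objective matches a brute-force angle grid", {
  set.seed(44)
  X1 <- scale(matrix(rnorm(10 * 2), 10, 2), scale = FALSE)
  X2 <- scale(matrix(rnorm(10 * 2) + 0.8 * X1[, c(1, 1)], 10, 2), scale = FALSE)
  fit <- fit_sgcca(list(a = X1, b = X2),
                   sgcca_config(n_components = 1, sparsity = c(1, 1),
                                scale = FALSE, seed = 4, tol = 1e-12))
  S <- crossprod(X1, X2) / (nrow(X1) - 1)
  theta <- seq(0, 2 * pi, by = 1e-3)
  A <- cbind(cos(theta), sin(theta))
  # |a1' S a2| over the product of unit circles, evaluated in chunks
  best <- 0
  M <- A %*% S
  for (chunk in split(seq_along(theta), ceiling(seq_along(theta) / 800))) {
    best <- max(best, abs(M %*% t(A[chunk, , drop = FALSE])))
  }
  expect_equal(fit$objective[1], best, tolerance = 1e-4)
})

test_that("without sparsity on whitened blocks, component 1 equals classical CCA", {
  set.seed(45)
  n <- 50
  Z <- matrix(rnorm(n), n, 1)
  X <- matrix(rnorm(n * 3), n, 3) + Z %*% matrix(c(1, 0.5, 0), 1, 3)
  Y <- matrix(rnorm(n * 3), n, 3) + Z %*% matrix(c(0.8, 0, 0.4), 1, 3)
  whiten <- function(M) {
    M <- scale(M, scale = FALSE)
    e <- eigen(crossprod(M) / (nrow(M) - 1), symmetric = TRUE)
    M %*% e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  }
  Xw <- whiten(X); Yw <- whiten(Y)
  fit <- fit_sgcca(list(x = Xw, y = Yw),
                   sgcca_config(n_components = 1, sparsity = c(1, 1),
                                scale = FALSE, seed = 5, tol = 1e-14,
                                max_iter = 5000))
  rho <- cancor(X, Y)$cor[1]
  expect_equal(abs(fit$component_correlation[1]), rho, tolerance = 1e-6)
})

test_that("sgcca agrees with the mixOmics implementation on a dense toy", {
  skip_if_not_installed("mixOmics")
  set.seed(46)
  n <- 30
  Z <- rnorm(n)
  X <- matrix(rnorm(n * 5), n, 5) + Z
  Y <- matrix(rnorm(n * 8), n, 8) + 0.9 * Z
  colnames(X) <- paste0("x", 1:5); colnames(Y) <- paste0("y", 1:8)
  fit <- fit_sgcca(list(X = X, Y = Y),
                   sgcca_config(n_components = 1, sparsity = c(1, 1),
                                scheme = "centroid", seed = 6, tol = 1e-12))
  design <- matrix(c(0, 1, 1, 0), 2, 2)
  ref <- mixOmics::wrapper.sgcca(list(X = X, Y = Y), design = design,
                                 penalty = c(1, 1), ncomp = 1,
                                 scheme = "centroid", scale = TRUE)
  a_ref <- ref$loadings$X[, 1] / sqrt(sum(ref$loadings$X[, 1]^2))
  b_ref <- ref$loadings$Y[, 1] / sqrt(sum(ref$loadings$Y[, 1]^2))
  expect_gt(abs(sum(fit$weights$X[, 1] * a_ref)), 1 - 1e-4)
  expect_gt(abs(sum(fit$weights$Y[, 1] * b_ref)), 1 - 1e-4)
})

test_that("variance explained is exact for a rank-1 gene block and tiny under the null", {
  set.seed(47)
  n <- 40
  score <- rnorm(n)
  G <- score %*% t(runif(30, 0.5, 2))          # genes = rank-1 in the score
  fit0 <- fit_sgcca(list(a = cbind(score), b = G),
                    sgcca_config(n_components = 1, sparsity = c(1, 1), seed = 7))
  ve <- variance_explained(fit0, G, chem_scores = cbind(score))
  expect_equal(ve$per_component[1], 1, tolerance = 1e-10)

  # independent scores explain ~1/(n-1) of a random gene block
  set.seed(48)
  n2 <- 1000
  Gnull <- matrix(rnorm(n2 * 50), n2, 50)
  snull <- cbind(rnorm(n2))
  ve0 <- variance_explained(fit0, Gnull, chem_scores = snull)
  expect_lt(ve0$per_component[1], 0.01)
})

test_that("cumulative variance explained equals the joint regression R^2", {
  set.seed(49)
  n <- 35
  S <- matrix(rnorm(n * 3), n, 3)
  G <- S %*% matrix(rnorm(3 * 20), 3, 20) + matrix(rnorm(n * 20), n, 20)
  ds <- small_synth(seed = 50, missing_rate = 0, lod_quantile = 0)
  dummy_fit <- fit_sgcca(list(a = S, b = G),
                         sgcca_config(n_components = 3, sparsity = c(1, 1), seed = 8))
  ve <- variance_explained(dummy_fit, G, chem_scores = S)
  Gc <- scale(G, scale = FALSE)
  resid <- lm.fit(x = cbind(1, S), y = G)$residuals
  r2_joint <- 1 - sum(resid^2) / sum(Gc^2)
  expect_equal(ve$cumulative[length(ve$cumulative)], r2_joint, tolerance = 1e-8)
})

test_that("planted sparse chemical support is recovered across seeds", {
  hits <- 0
  for (seed in 1:3) {
    cfg <- synth_config(n_samples = 100, n_chemicals = 50, n_genes = 300,
                        n_factors = 1, chem_sparsity = 0.1, n_modules = 1,
                        module_size_range = c(80, 120), factor_effect = 1,
                        noise_sd_chem = 0.3, missing_rate = 0, lod_quantile = 0,
                        seed = seed)
    ds <- generate_dataset(cfg)
    chem <- standardize_chemicals(ds$chem)
    norm <- normalize_expression(filter_genes(ds$expr)$expr)
    fit <- fit_sgcca(list(chem = unclass_mat(chem), genes = t(unclass_mat(norm))),
                     sgcca_config(n_components = 1, sparsity = c(0.31, 0.3),
                                  seed = seed))
    w <- fit$weights$chem[, 1]
    planted <- which(ds$truth$chem_loadings[, 1] != 0)
    est <- which(w != 0)
    jac <- length(intersect(est, planted)) / length(union(est, planted))
    lp <- ds$truth$chem_loadings[, 1]
    lp <- lp / sqrt(sum(lp^2))
    if (jac >= 0.9 && abs(sum(w * lp)) >= 0.95) hits <- hits + 1
  }
  expect_gte(hits, 2)
})

test_that("rank-exhausted blocks stop early with a warning", {
  set.seed(51)
  x <- matrix(rnorm(20), 20, 1)
  y <- matrix(rnorm(20 * 2), 20, 2)
  expect_warning(
    fit <- fit_sgcca(list(a = x, b = y),
                     sgcca_config(n_components = 3, sparsity = c(1, 1), seed = 9)),
    "rank|component")
  expect_lt(fit$n_components, 3)
})
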