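test_that("benjamini-hochberg reproduces hand-computed step-up values", {
  # m = 3: adj = min_j>=i (3 p_j / j) -> (0.03, 0.03, 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")
  # order preservation: adjustment is monotone in the raw p-values
  set.seed(60)
  p <- runif(50)
  adj <- benjamini_hochberg(p)
  expect_true(all(adj >= p - 1e-15))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("the exact Mann-Whitney branch reproduces the enumerated 2-vs-3 case", {
  # module {0.4, 0.3} vs out-group {0.1, 0.1, 0.1}: U = 6; only 1 of the
  # C(5,2) = 10 group assignments reaches U >= 6, so p = 0.1
  res <- chemolink:::mw_greater(c(0.4, 0.3), c(0.1, 0.1, 0.1))
  expect_equal(res$U, 6)
  expect_equal(res$p_value, 0.1)
})

test_that("all-tied squared weights give the central U and no significance", {
  # with every value tied the rank variance collapses, so the one-sided
  # p-value degenerates to 1: maximally non-significant
  x <- rep(0.2, 20); y <- rep(0.2, 60)
  res <- chemolink:::mw_greater(x, y, method = "normal")
  expect_equal(res$U, 20 * 60 / 2)
  expect_gte(res$p_value, 0.5)
})

test_that("exact and normal branches agree within 0.02 at n1 = n2 = 8", {
  set.seed(61)
  for (i in 1:10) {
    x <- rnorm(8, mean = runif(1, 0, 1)); y <- rnorm(8)
    pe <- chemolink:::mw_greater(x, y, method = "exact")$p_value
    pn <- chemolink:::mw_greater(x, y, method = "normal")$p_value
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("module enrichment flags the module with planted large squared weights", {
  set.seed(62)
  genes <- paste0("g", 1:120)
  assignment <- setNames(rep(c(1L, 2L, 3L), each = 40), genes)
  partition <- structure(list(assignment = assignment,
                              sizes = c(`1` = 40L, `2` = 40L, `3` = 40L)),
                         class = "module_partition")
  sw <- setNames(abs(rnorm(120, sd = 0.01)), genes)
  sw[assignment == 2] <- sw[assignment == 2] + 0.05
  tab <- module_enrichment(sw, partition)
  expect_equal(nrow(tab), 3)
  expect_true(tab$significant[tab$module == 2])
  expect_false(any(tab$significant[tab$module != 2]))
  expect_true(all(tab$p_adjusted >= tab$p_value - 1e-15))
  expect_true(all(tab$p_adjusted >= 0 & tab$p_adjusted <= 1))
})

test_that("module enrichment requires an out-group and full SW coverage", {
  genes <- paste0("g", 1:10)
  partition <- structure(list(assignment = setNames(rep(1L, 10), genes),
                              sizes = c(`1` = 10L)),
                         class = "module_partition")
  sw <- setNames(runif(10), genes)
  expect_error(module_enrichment(sw, partition), "out-group")
  part2 <- structure(list(assignment = setNames(c(rep(1L, 5), rep(2L, 5)), genes),
                          sizes = c(`1` = 5L, `2` = 5L)),
                     class = "module_partition")
  expect_error(module_enrichment(sw[1:8], part2), "missing")
})

test_that("chi-square equals the direct formula and vanishes under proportionality", {
  universe <- paste0("g", 1:1000)
  module <- universe[1:50]
  # pathway split exactly proportionally: 5/50 in module, 95/950 outside
  prop_path <- c(universe[1:5], universe[51:145])
  ann <- structure(list(prop = prop_path), class = "pathway_annotation")
  tab <- pathway_overrepresentation(module, universe, ann)
  expect_equal(tab$chi_square[1], 0, tolerance = 1e-10)
  expect_equal(tab$p_value[1], 1, tolerance = 1e-10)
  expect_false(tab$enriched[1])

  # hand-evaluated chi-square for the 2x2 table (10, 40, 10, 940)
  o <- matrix(c(10, 40, 10, 940), 2, 2)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  chi_hand <- sum((o - e)^2 / e)
  universe2 <- paste0("g", 1:1000)
  module2 <- universe2[1:50]
  path2 <- c(universe2[1:10], universe2[51:60])      # a=10, c=10
  ann2 <- structure(list(p2 = path2), class = "pathway_annotation")
  tab2 <- pathway_overrepresentation(module2, universe2, ann2)
  expect_equal(tab2$in_module_in_pathway, 10)
  expect_equal(tab2$not_module_in_pathway, 10)
  expect_equal(tab2$chi_square[1], chi_hand, tolerance = 1e-10)
  expect_true(tab2$enriched[1])
})

test_that("chi-square equals the squared two-proportion z statistic", {
  set.seed(63)
  universe <- paste0("g", 1:400)
  module <- universe[1:80]
  for (i in 1:5) {
    path <- sample(universe, 60)
    ann <- structure(list(pw = path), class = "pathway_annotation")
    tab <- pathway_overrepresentation(module, universe, ann, min_overlap = 1)
    if (nrow(tab) == 0) next
    a <- tab$in_module_in_pathway; b <- tab$in_module_not_pathway
    c2 <- tab$not_module_in_pathway; d <- tab$not_module_not_pathway
    p1 <- a / (a + b); p2 <- c2 / (c2 + d)
    pp <- (a + c2) / (a + b + c2 + d)
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / (a + b) + 1 / (c2 + d)))
    expect_equal(tab$chi_square, z^2, tolerance = 1e-8)
  }
})

test_that("a pathway fully inside an equal-size module maximizes the chi-square", {
  universe <- paste0("g", 1:300)
  module <- universe[1:30]
  size <- 30
  set.seed(64)
  anns <- list(inside = universe[1:30])              # exactly the module
  for (i in 1:10) anns[[paste0("rand", i)]] <- sample(universe, size)
  class(anns) <- "pathway_annotation"
  tab <- pathway_overrepresentation(module, universe, anns, min_overlap = 1)
  expect_equal(tab$pathway[which.max(tab$chi_square)], "inside")
})

test_that("low-overlap pathways are skipped and logged; empty universe errors", {
  universe <- paste0("g", 1:100)
  module <- universe[1:20]
  anns <- structure(list(tiny = universe[c(1, 30, 40)],      # overlap 1
                         ok = universe[1:10]),
                    class = "pathway_annotation")
  tab <- pathway_overrepresentation(module, universe, anns, min_overlap = 3)
  expect_equal(tab$pathway, "ok")
  expect_equal(attr(tab, "skipped"), "tiny")
  expect_error(pathway_overrepresentation(character(0), character(0), anns),
               "empty")
})

test_that("gmt files round-trip and malformed lines are rejected", {
  sets <- structure(list(pw1 = c("g1", "g2", "g3"), pw2 = c("g4", "g5")),
                    class = "pathway_annotation")
  attr(sets, "description") <- c(pw1 = "first pathway", pw2 = "second")
  path <- write_toy_gmt(sets)
  back <- read_gmt(path)
  expect_equal(back$pw1, sets$pw1)
  expect_equal(attr(back, "description")[["pw2"]], "second")
  bad <- tempfile(fileext = ".gmt")
  writeLines("lonely_id", bad)
  expect_error(read_gmt(bad), "fewer than 3")
})

test_that("the link report lists exactly the above-cutoff chemicals per component", {
  ds <- small_synth(seed = 65, missing_rate = 0, lod_quantile = 0)
  chem <- standardize_chemicals(ds$chem)
  norm <- normalize_expression(filter_genes(ds$expr)$expr)
  fit <- fit_sgcca(list(chemicals = unclass_mat(chem), genes = t(unclass_mat(norm))),
                   sgcca_config(n_components = 2, sparsity = c(0.5, 0.3), seed = 10))
  net <- suppressWarnings(build_consensus_network(norm,
          ensemble_config(n_runs = 5, candidate_thresholds = seq(0.35, 0.6, 0.05),
                          seed = 66)))
  part <- detect_modules(net, seed = 11)
  enr <- module_enrichment(fit$squared_weights$genes, part)
  rep <- link_report(fit, enr, sw_cutoff = 0.01)
  for (k in 1:2) {
    sw <- fit$squared_weights$chemicals[, k]
    expect_setequal(rep[[k]]$chemicals$variable, names(sw)[sw > 0.01])
    expect_setequal(rep[[k]]$modules,
                    enr$module[enr$component == k & enr$significant])
  }
  # serialization produces both artifacts
  dir <- tempfile("report_")
  paths <- write_link_report(rep, dir)
  expect_true(all(file.exists(paths)))
})

test_that("a fit with all chemical SW below cutoff yields an empty contributor list", {
  # perfectly diffuse unit-norm weights over 200 chemicals: SW = 0.005 each
  p <- 200
  w <- matrix(rep(1 / sqrt(p), p), p, 1,
              dimnames = list(paste0("C", 1:p), NULL))
  fit <- structure(list(weights = list(chem = w),
                        squared_weights = list(chem = w^2),
                        n_components = 1L), class = "sgcca_fit")
  expect_equal(nrow(sw_contributors(fit, "chem", 1, 0.01)), 0)
})
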