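#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false-discovery-rate adjustment: sort the m p-values ascending,
#' set `adj_i = min_{j >= i} (m * p_j / j)` clipped to 1, and return values
#' in the input order.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in input order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' One-sided Mann-Whitney test by enumeration or normal approximation
#'
#' Tests whether `x` is stochastically larger than `y`. When the smaller
#' group has at most `exact_max` observations and the number of group
#' assignments is enumerable, the p-value is exact: every assignment of the
#' pooled values to the two groups is enumerated and `P(U >= U_obs)`
#' computed directly (ties handled exactly via average ranks). Otherwise the
#' normal approximation with tie and continuity correction is used (via
#' [stats::wilcox.test()]).
#'
#' @param x,y Numeric vectors.
#' @param method `"auto"` (default), `"exact"` or `"normal"`.
#' @param exact_max Largest small-group size for the exact branch.
#' @return List with `U` and `p_value`.
#' @keywords internal
mw_greater <- function(x, y, method = c("auto", "exact", "normal"),
                       exact_max = 8) {
  method <- match.arg(method)
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled, ties.method = "average")
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (method == "auto") {
    method <- if (min(n1, n2) <= exact_max &&
                  choose(n1 + n2, min(n1, n2)) <= 1e5) "exact" else "normal"
  }
  if (method == "exact") {
    small_first <- n1 <= n2
    m <- min(n1, n2)
    combs <- utils::combn(n1 + n2, m)
    tot <- n1 * n2
    U_all <- apply(combs, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
    if (!small_first) U_all <- tot - U_all  # U of group x from complement
    p <- mean(U_all >= U_obs - 1e-12)
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "greater",
                         exact = FALSE, correct = TRUE))
    p <- wt$p.value
  }
  list(U = U_obs, p_value = p)
}

#' Mann-Whitney enrichment of squared weights within coexpression modules
#'
#' For each module and component, tests whether the module's genes have
#' stochastically larger squared weights than genes outside the module
#' (one-sided Mann-Whitney U). The p-value is exact (by enumeration of group
#' assignments, see [mw_greater()]) when the smaller group has at most 8
#' observations, otherwise a normal approximation with tie and continuity
#' correction is used. P-values are adjusted by Benjamini-Hochberg in a
#' single family pooled over all (module, component) pairs by default; set
#' `family = "per_component"` for per-LDR families.
#'
#' @param sw Squared weights for the gene block: either a genes x components
#'   matrix or a named vector (one component). Must cover every partitioned
#'   gene.
#' @param partition A `module_partition` from [detect_modules()].
#' @param alpha FDR level (default 0.05).
#' @param family BH family: `"pooled"` (default) or `"per_component"`.
#' @return A `module_enrichment_table` data frame with one row per
#'   (module, component): U statistic, one-sided `p_value`, `p_adjusted`,
#'   `median_sw_in`, `median_sw_out`, `module_size`, `significant`.
#' @export
module_enrichment <- function(sw, partition, alpha = 0.05,
                              family = c("pooled", "per_component")) {
  stopifnot(inherits(partition, "module_partition"))
  family <- match.arg(family)
  if (is.null(dim(sw))) sw <- matrix(sw, ncol = 1, dimnames = list(names(sw), NULL))
  assigned <- partition$assignment[!is.na(partition$assignment)]
  if (!all(names(assigned) %in% rownames(sw))) {
    stop("squared weights missing for some partitioned genes")
  }
  modules <- sort(unique(assigned))
  rows <- list()
  for (comp in seq_len(ncol(sw))) {
    x <- sw[, comp]
    for (m in modules) {
      in_genes <- names(assigned)[assigned == m]
      out_genes <- setdiff(rownames(sw), in_genes)
      if (length(out_genes) == 0) stop("module equals the entire gene set: no out-group")
      xi <- x[in_genes]; xo <- x[out_genes]
      wt <- mw_greater(xi, xo)
      rows[[length(rows) + 1]] <- data.frame(
        module = m, component = comp,
        U = wt$U, p_value = wt$p_value,
        median_sw_in = stats::median(xi), median_sw_out = stats::median(xo),
        module_size = length(xi))
    }
  }
  tab <- do.call(rbind, rows)
  if (family == "pooled") {
    tab$p_adjusted <- benjamini_hochberg(tab$p_value)
  } else {
    tab$p_adjusted <- NA_real_
    for (comp in unique(tab$component)) {
      i <- tab$component == comp
      tab$p_adjusted[i] <- benjamini_hochberg(tab$p_value[i])
    }
  }
  tab$significant <- tab$p_adjusted < alpha
  class(tab) <- c("module_enrichment_table", "data.frame")
  tab
}

#' Chi-square pathway overrepresentation within a gene module
#'
#' For each pathway, forms the 2x2 table (in module / not) x (in pathway /
#' not) over the analyzed gene universe and applies Pearson's chi-square
#' test without continuity correction. Pathways overlapping the module in
#' fewer than `min_overlap` genes are skipped (recorded in attribute
#' `skipped`). P-values are BH-adjusted across tested pathways; a pathway is
#' enriched iff adjusted p < alpha and the observed overlap exceeds its
#' expectation. Cells with expected count < 5 are flagged, not dropped.
#'
#' @param module_genes Character vector of module gene ids (subset of
#'   `universe`).
#' @param universe Character vector: all analyzed genes.
#' @param annotation A `pathway_annotation` from [read_gmt()] (or any named
#'   list of gene-id vectors); genes outside the universe are dropped.
#' @param alpha FDR level (default 0.05).
#' @param min_overlap Minimum module-pathway overlap to test (default 3).
#' @return A `pathway_table` data frame: pathway, the four 2x2 counts,
#'   `chi_square`, `p_value`, `p_adjusted`, `expected_overlap`,
#'   `low_expected_cell` flag, `enriched`.
#' @export
pathway_overrepresentation <- function(module_genes, universe, annotation,
                                       alpha = 0.05, min_overlap = 3) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty gene universe")
  if (!all(module_genes %in% universe)) {
    stop("module genes must be a subset of the universe")
  }
  module_genes <- unique(module_genes)
  n_u <- length(universe)
  n_m <- length(module_genes)
  rows <- list(); skipped <- character(0)
  for (pw in names(annotation)) {
    genes <- intersect(annotation[[pw]], universe)
    if (length(genes) == 0) { skipped <- c(skipped, pw); next }
    a <- length(intersect(module_genes, genes))      # in module, in pathway
    if (a < min_overlap) { skipped <- c(skipped, pw); next }
    b <- n_m - a                                     # in module, not pathway
    c2 <- length(genes) - a                          # not module, in pathway
    d <- n_u - a - b - c2
    tab <- matrix(c(a, b, c2, d), 2, 2)
    expected <- outer(rowSums(tab), colSums(tab)) / n_u
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    rows[[length(rows) + 1]] <- data.frame(
      pathway = pw, in_module_in_pathway = a, in_module_not_pathway = b,
      not_module_in_pathway = c2, not_module_not_pathway = d,
      chi_square = unname(ct$statistic), p_value = ct$p.value,
      expected_overlap = expected[1, 1],
      low_expected_cell = any(expected < 5),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    out <- data.frame(pathway = character(0), in_module_in_pathway = integer(0),
                      in_module_not_pathway = integer(0),
                      not_module_in_pathway = integer(0),
                      not_module_not_pathway = integer(0),
                      chi_square = numeric(0), p_value = numeric(0),
                      expected_overlap = numeric(0),
                      low_expected_cell = logical(0),
                      p_adjusted = numeric(0), enriched = logical(0))
  } else {
    out <- do.call(rbind, rows)
    out$p_adjusted <- benjamini_hochberg(out$p_value)
    out$enriched <- out$p_adjusted < alpha &
      out$in_module_in_pathway > out$expected_overlap
  }
  attr(out, "skipped") <- skipped
  class(out) <- c("pathway_table", "data.frame")
  out
}

#' Per-component summary linking chemicals, modules and pathways
#'
#' Assembles, for each component (LDR): the contributing chemicals (squared
#' weight above `sw_cutoff`, ranked by squared weight), the significantly
#' enriched coexpression modules, and the pathways overrepresented in those
#' modules.
#'
#' @param fit An `sgcca_fit` whose first block is the chemical block and
#'   second block the gene block.
#' @param enrichment A `module_enrichment_table` over the same fit.
#' @param pathways Optional combined `pathway_table` with `module` and
#'   `component` columns (as produced by [run_pipeline()]), or `NULL`.
#' @param sw_cutoff Squared-weight cutoff for chemical contributors
#'   (default 0.01).
#' @return A `link_report`: list with one element per component, each a list
#'   with `chemicals` (data frame variable, sw), `modules` (significant
#'   module ids) and `pathways` (enriched pathway ids).
#' @export
link_report <- function(fit, enrichment, pathways = NULL, sw_cutoff = 0.01) {
  stopifnot(inherits(fit, "sgcca_fit"),
            inherits(enrichment, "module_enrichment_table"))
  gene_sw <- fit$squared_weights[[2]]
  enr_genes <- max(enrichment$module_size) # sanity: enrichment is over some partition
  if (nrow(gene_sw) < enr_genes) {
    stop("mismatched gene universes between fit and enrichment table")
  }
  out <- lapply(seq_len(fit$n_components), function(comp) {
    chems <- sw_contributors(fit, block = 1, component = comp,
                             sw_cutoff = sw_cutoff)
    mods <- enrichment$module[enrichment$component == comp & enrichment$significant]
    pws <- character(0)
    if (!is.null(pathways) && nrow(pathways) > 0 &&
        all(c("module", "component") %in% names(pathways))) {
      pws <- unique(pathways$pathway[pathways$component == comp &
                                       pathways$enriched])
    }
    list(chemicals = chems, modules = mods, pathways = pws)
  })
  names(out) <- paste0("LDR", seq_len(fit$n_components))
  class(out) <- "link_report"
  out
}

#' @export
print.link_report <- function(x, ...) {
  for (ldr in names(x)) {
    cat(sprintf("%s: %d contributing chemical(s), %d significant module(s), %d enriched pathway(s)\n",
                ldr, nrow(x[[ldr]]$chemicals), length(x[[ldr]]$modules),
                length(x[[ldr]]$pathways)))
  }
  invisible(x)
}

#' Write a link report as TSV plus a plain-text summary
#'
#' @param report A `link_report`.
#' @param directory Output directory.
#' @return Named file paths, invisibly.
#' @export
write_link_report <- function(report, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (ldr in names(report)) {
    el <- report[[ldr]]
    if (nrow(el$chemicals)) {
      rows[[length(rows) + 1]] <- data.frame(
        component = ldr, kind = "chemical",
        id = el$chemicals$variable,
        value = el$chemicals$sw, stringsAsFactors = FALSE)
    }
    if (length(el$modules)) {
      rows[[length(rows) + 1]] <- data.frame(
        component = ldr, kind = "module", id = as.character(el$modules),
        value = NA_real_, stringsAsFactors = FALSE)
    }
    if (length(el$pathways)) {
      rows[[length(rows) + 1]] <- data.frame(
        component = ldr, kind = "pathway", id = el$pathways,
        value = NA_real_, stringsAsFactors = FALSE)
    }
  }
  tsv <- file.path(directory, "link_report.tsv")
  if (length(rows)) write_tsv(do.call(rbind, rows), tsv)
  else write_tsv(data.frame(component = character(0), kind = character(0),
                            id = character(0), value = numeric(0)), tsv)
  txt <- file.path(directory, "link_report.txt")
  con <- file(txt, "w"); on.exit(close(con))
  for (ldr in names(report)) {
    el <- report[[ldr]]
    writeLines(sprintf("## %s", ldr), con)
    writeLines(sprintf("contributing chemicals (SW > cutoff): %s",
                       if (nrow(el$chemicals)) paste(el$chemicals$variable, collapse = ", ")
                       else "none"), con)
    writeLines(sprintf("significant modules: %s",
                       if (length(el$modules)) paste(el$modules, collapse = ", ")
                       else "none"), con)
    writeLines(sprintf("enriched pathways: %s",
                       if (length(el$pathways)) paste(el$pathways, collapse = ", ")
                       else "none"), con)
    writeLines("", con)
  }
  invisible(c(tsv = tsv, txt = txt))
}
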