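#!/usr/bin/env Rscript
# Stage 5: module enrichment and pathway overrepresentation.
#
# Mann-Whitney tests of gene squared weights inside vs outside each module
# per LDR (BH-adjusted, pooled family); chi-square overrepresentation of a
# synthetic pathway annotation in the significant modules; final per-LDR
# link report. The annotation is synthetic: half its gene sets are drawn
# from planted modules, half at random, so overrepresentation has known
# positives.

library(chemolink)

norm <- read_expr_matrix("results/expression_normalized.tsv", normalized = TRUE)
modules <- utils::read.table("results/modules.tsv", header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
part <- structure(list(
  assignment = stats::setNames(modules$module_id, modules$gene_id),
  sizes = sort(table(modules$module_id), decreasing = TRUE)),
  class = "module_partition")

# rebuild the fitted squared weights from stage 4's artifacts
sw_tab <- utils::read.table("results/sgcca/squared_weights_genes.tsv",
                            header = TRUE, sep = "\t", check.names = FALSE)
sw <- as.matrix(sw_tab[, -1]); rownames(sw) <- sw_tab$variable
w_tab <- utils::read.table("results/sgcca/weights_chemicals.tsv",
                           header = TRUE, sep = "\t", check.names = FALSE)
w_chem <- as.matrix(w_tab[, -1]); rownames(w_chem) <- w_tab$variable
fit <- structure(list(weights = list(chemicals = w_chem, genes = sqrt(sw)),
                      squared_weights = list(chemicals = w_chem^2, genes = sw),
                      n_components = ncol(sw)), class = "sgcca_fit")

enr <- module_enrichment(sw, part, alpha = 0.05)
utils::write.table(enr, "results/module_enrichment.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("module enrichment: %d of %d (module, LDR) pairs significant\n",
            sum(enr$significant), nrow(enr)))

# synthetic annotation with planted positives
set.seed(2026)
truth <- utils::read.table("results/data/truth_modules.tsv", header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
universe <- rownames(norm)
sets <- list()
for (m in sort(unique(truth$module_id[truth$module_id > 0]))) {
  members <- intersect(truth$gene_id[truth$module_id == m], universe)
  if (length(members) >= 20) {
    sets[[sprintf("planted_module_%d", m)]] <- sample(members,
                                                      min(40, length(members)))
  }
}
for (i in 1:8) sets[[sprintf("random_%d", i)]] <- sample(universe, 40)
class(sets) <- "pathway_annotation"
write_gmt(sets, "results/synthetic_annotation.gmt")

sig <- unique(enr[enr$significant, c("module", "component")])
all_rows <- list()
for (i in seq_len(nrow(sig))) {
  mg <- names(part$assignment)[!is.na(part$assignment) &
                                 part$assignment == sig$module[i]]
  pt <- pathway_overrepresentation(mg, universe, sets, alpha = 0.05)
  if (nrow(pt)) {
    pt$module <- sig$module[i]; pt$component <- sig$component[i]
    all_rows[[length(all_rows) + 1]] <- pt
  }
}
pw <- if (length(all_rows)) do.call(rbind, all_rows) else NULL
if (!is.null(pw)) {
  class(pw) <- c("pathway_table", "data.frame")
  utils::write.table(pw, "results/pathway_overrepresentation.tsv", sep = "\t",
                     quote = FALSE, row.names = FALSE)
  hits <- unique(pw$pathway[pw$enriched])
  cat(sprintf("pathways enriched in significant modules: %s\n",
              if (length(hits)) paste(hits, collapse = ", ") else "none"))
}

rep <- link_report(fit, enr, pathways = pw, sw_cutoff = 0.01)
write_link_report(rep, "results")
print(rep)
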