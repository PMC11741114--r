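#!/usr/bin/env Rscript
# Stage 4: sparse generalized canonical correlation between the blocks.
#
# Five components (low-dimension representations, LDRs); chemical block
# sparsity 0.5, gene block 0.3; centroid scheme. Reports per-LDR score
# correlations, the chemicals contributing SW > 0.01, and the fraction of
# gene-block variance explained by the chemical-side scores.

library(chemolink)

chem <- read_chem_table("results/chemicals_processed.tsv")
norm <- read_expr_matrix("results/expression_normalized.tsv", normalized = TRUE)

fit <- fit_sgcca(list(chemicals = chem, genes = t(norm)),
                 sgcca_config(n_components = 5, sparsity = c(0.5, 0.3),
                              scheme = "centroid", seed = 2026))
write_sgcca_fit(fit, "results/sgcca")

cat(sprintf("LDR score correlations: %s\n",
            paste(sprintf("%.2f", fit$component_correlation), collapse = ", ")))
for (k in seq_len(fit$n_components)) {
  contrib <- sw_contributors(fit, "chemicals", k, 0.01)
  cat(sprintf("LDR%d: %d chemicals with SW > 0.01 (top: %s)\n", k,
              nrow(contrib),
              paste(utils::head(contrib$variable, 3), collapse = ", ")))
}
ve <- variance_explained(fit, t(norm))
cat(sprintf("gene-block variance explained per LDR: %s (cumulative %.1f%%)\n",
            paste(sprintf("%.1f%%", 100 * ve$per_component), collapse = ", "),
            100 * ve$cumulative[length(ve$cumulative)]))
utils::write.table(
  data.frame(component = seq_along(ve$per_component),
             variance_explained = ve$per_component,
             cumulative = ve$cumulative),
  "results/variance_explained.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
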