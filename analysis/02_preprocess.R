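#!/usr/bin/env Rscript
# Stage 2: preprocess both blocks from the persisted stage-1 files.
#
# Chemical block: detection filter (missing in > 50% of samples excluded),
# kNN imputation (k = 5), per-chemical standardization, PCA ordination.
# Gene block: count filter (mean >= 5, total >= 10, zeros <= 60%), log-CPM
# plus full quantile normalization.

library(chemolink)

chem <- read_chem_table("results/data/chemicals.tsv")
expr <- read_expr_matrix("results/data/counts.tsv")

filt <- filter_chemicals(chem, max_missing_frac = 0.5)
cat(sprintf("chemical filter: %d of %d chemicals retained (%d excluded)\n",
            filt$report$n_retained, filt$report$n_input, filt$report$n_excluded))
write_tsv_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
write_tsv_report(filt$report$exclusions, "results/chemical_exclusions.tsv")

imp <- knn_impute(filt$table, k = 5)
std <- standardize_chemicals(imp)
write_chem_table(std, "results/chemicals_processed.tsv")

qc <- pca_qc(std, n_components = 5)
cat(sprintf("chemical PCA: first two components explain %.1f%% and %.1f%% of variance\n",
            100 * qc$explained_variance[1], 100 * qc$explained_variance[2]))
write_tsv_report(data.frame(sample_id = rownames(qc$scores), qc$scores,
                            check.names = FALSE),
                 "results/chemical_pca_scores.tsv")

gf <- filter_genes(expr)
cat(sprintf("gene filter: %d of %d genes retained (low mean %d, low total %d, sparse %d)\n",
            gf$report$n_retained, gf$report$n_input, gf$report$low_mean,
            gf$report$low_total, gf$report$too_many_zeros))
norm <- normalize_expression(gf$expr, method = "log_cpm_quantile")
write_expr_matrix(norm, "results/expression_normalized.tsv")
cat("wrote results/chemicals_processed.tsv and results/expression_normalized.tsv\n")
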