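#!/usr/bin/env Rscript

# Quality control and PCA for each simulated dataset: missing-data filter
# (> 5% removed), iterative 10-SD outlier removal on the top 10 PCs, then
# standardization and eigen-decomposition. Writes per-dataset PC1-PC2
# scores and a variance-explained summary.

suppressPackageStartupMessages(library(genogeo))

out_root <- "results"
summary_rows <- list()

for (name in c("strong", "weak")) {
  dir <- file.path(out_root, "data", name)
  G <- load_genotype_matrix(file.path(dir, "genotypes.tsv"), "tsv",
                            file.path(dir, "popmap.tsv"))
  qc <- run_qc(G)
  pca <- genotype_pca(qc$genotypes)

  scores <- data.frame(individual_id = rownames(pca$scores),
                       population = unname(qc$genotypes$population_of),
                       PC1 = pca$scores[, 1], PC2 = pca$scores[, 2])
  write.table(scores, file.path(out_root, paste0(name, "_pc_scores.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  summary_rows[[name]] <- data.frame(
    dataset = name,
    n_initial = n_individuals(G),
    n_after_qc = n_individuals(qc$genotypes),
    n_high_missing = length(qc$removed_high_missing),
    n_outliers = nrow(qc$removed_outliers),
    qc_iterations = qc$iterations,
    pc1_variance_pct = 100 * pca$variance_explained[1],
    pc2_variance_pct = 100 * pca$variance_explained[2])
  cat(sprintf("%s: %d -> %d individuals; PC1 %.2f%%, PC2 %.2f%%\n",
              name, n_individuals(G), n_individuals(qc$genotypes),
              100 * pca$variance_explained[1],
              100 * pca$variance_explained[2]))
}

write.table(do.call(rbind, summary_rows),
            file.path(out_root, "qc_pca_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
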