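#!/usr/bin/env Rscript
# Step 7: single-cell stage — QC filtering, depth normalization,
# per-cell CCN-network activity (recovery-curve AUC and the rank-sum
# alternative), population proportions over time, and sender -> receiver
# ligand-receptor strength between mesenchymal and chondrocyte
# populations.

suppressPackageStartupMessages(library(ccnnet))

fix_dir <- "results/fixtures"
out_dir <- "results/07_single_cell"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

counts <- as(Matrix::readMM(file.path(fix_dir, "matrix.mtx")), "CsparseMatrix")
genes <- readLines(file.path(fix_dir, "genes.tsv"))
meta <- read_tsv(file.path(fix_dir, "cells.tsv"))
dimnames(counts) <- list(meta$cell, genes)
mito_genes <- grep("^MT-", genes, value = TRUE)

# fixture-scaled thresholds; the full-scale profiles are in qc_profiles()
q <- qc_filter(counts, meta, mito_genes, min_genes = 50, max_genes = 270,
               max_mito = 0.05, min_cells_per_gene = 3)
cat(sprintf("QC: %d of %d cells kept (%d low-gene, %d high-gene, %d high-mito removed); %d genes kept\n",
            q$report$cells_kept, nrow(counts), q$report$removed_min_genes,
            q$report$removed_max_genes, q$report$removed_max_mito,
            q$report$genes_kept))
jsonlite::write_json(q$report, file.path(out_dir, "qc_report.json"),
                     auto_unbox = TRUE, pretty = TRUE)

nm <- normalize_log(q$counts)
active_set <- grep("^ACT", colnames(nm), value = TRUE)

au <- aucell_score(nm, active_set, top_frac = 0.1)
rs <- rank_sum_score(nm, active_set, max_rank = 150)
pop <- setNames(q$cell_meta$population, q$cell_meta$cell)[rownames(nm)]
for (s in list(au, rs)) {
  means <- sort(tapply(s$score, pop, mean), decreasing = TRUE)
  cat(sprintf("%s activity by population: %s\n", s$method,
              paste(sprintf("%s=%.3f", names(means), means), collapse = " ")))
}
write_tsv(data.frame(cell = rownames(nm), population = pop,
                     auc = au$score, rank_sum = rs$score),
          file.path(out_dir, "activity_scores.tsv"))

pp <- population_proportions(q$cell_meta)
write_tsv(pp, file.path(out_dir, "population_proportions.tsv"))

pairs <- data.frame(ligand = c("CCN1", "BG0001", "BG0005"),
                    receptor = c("ITGB1", "BG0002", "BG0006"))
lr <- lr_strength(nm, q$cell_meta, pairs,
                  senders = c("mesenchyme_1", "mesenchyme_2"),
                  receivers = c("chondrocytes_1", "chondrocytes_2"))
cat(sprintf("strongest ligand-receptor signal: %s -> %s via %s-%s (strength %.2f)\n",
            lr$sender[1], lr$receiver[1], lr$ligand[1], lr$receptor[1],
            lr$strength[1]))
write_tsv(lr, file.path(out_dir, "lr_strength.tsv"))

# bulk trajectory summaries alongside: percent-of-day-1 for the seeds
expr <- read_expression_tsv(file.path(fix_dir, "human_expression.tsv"))
smeta <- read_tsv(file.path(fix_dir, "human_samples.tsv"))
day <- setNames(smeta$day, smeta$sample)
pc <- pca_scores(expr)
cors <- vapply(1:3, function(j) {
  abs(cor(pc$scores[, j], day[rownames(pc$scores)]))
}, numeric(1))
cat(sprintf("bulk PCA: top 3 components explain %.0f%% of variance; maturation axis is PC%d (|cor with day| = %.2f)\n",
            100 * sum(pc$variance_explained[1:3]), which.max(cors),
            max(cors)))
write_tsv(data.frame(sample = rownames(pc$scores), pc$scores,
                     check.names = FALSE),
          file.path(out_dir, "bulk_pca_scores.tsv"))
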