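#!/usr/bin/env Rscript
# Step 1: simulate the full multi-species study — bulk chondrogenesis
# time courses with planted co-expression modules hosting the CCN seed
# genes, STRING-style PPI graphs, ortholog tables, gene sets and a
# single-cell experiment with a planted high-activity population — and
# write every input the downstream steps read.

suppressPackageStartupMessages(library(ccnnet))

seed <- 20260919
fix_dir <- "results/fixtures"

bulk <- generate_bulk_multispecies(n_genes = 120,
                                   timepoints = c(1, 4, 7, 10),
                                   reps_per_timepoint = 3,
                                   n_modules = 3, module_size = 30,
                                   trait_effect = 1, noise_sd = 0.3,
                                   seed = seed)
ppi <- lapply(bulk, function(x) generate_ppi(x$truth, p_within = 0.8,
                                             p_between = 0.05,
                                             seed = seed + 1))
ortho <- generate_orthologs_and_genesets(bulk$human$truth, bulk$mouse$truth,
                                         frac_one2one = 0.7,
                                         frac_species_only = 0.15,
                                         seed = seed + 2)
sc <- generate_singlecell(n_cells = 400, seed = seed + 3)

write_fixture_bundle(fix_dir, bulk, ppi = ppi, ortho = ortho, sc = sc)

for (sp in names(bulk)) {
  tr <- bulk[[sp]]$truth
  cat(sprintf("%s: %d genes, %d samples, seeds [%s] planted in module M1\n",
              sp, nrow(bulk[[sp]]$expr), ncol(bulk[[sp]]$expr),
              paste(tr$seed_genes, collapse = ", ")))
}
cat(sprintf("orthologs: %d rows (%d planted one-to-one)\n",
            nrow(ortho$orthologs),
            sum(ortho$type_of_index == "one2one")))
cat(sprintf("single-cell: %d cells x %d genes, active population '%s'\n",
            nrow(sc$counts), ncol(sc$counts), sc$truth$active_population))
cat("fixture bundle written to", fix_dir, "\n")
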