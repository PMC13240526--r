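#!/usr/bin/env Rscript
# Step 3: build the CCN-centered regulatory network per species — load
# STRING-style edges at the 0.4 confidence threshold, restrict to the
# seed-containing modules, take first neighbors of the CCN genes, merge
# across modules and rank hubs by degree.

suppressPackageStartupMessages(library(ccnnet))

fix_dir <- "results/fixtures"
mod_dir <- "results/02_modules"
out_dir <- "results/03_networks"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

for (sp in c("human", "mouse", "chicken")) {
  ppi <- load_string_edges(file.path(fix_dir, paste0(sp, "_string_edges.tsv")),
                           threshold = 0.4)
  part <- read_tsv(file.path(mod_dir, paste0(sp, "_partition.tsv")))
  partition <- setNames(part$module, part$gene)
  seed_mods <- read_tsv(file.path(mod_dir, paste0(sp, "_seed_modules.tsv")))
  seeds <- default_seed_genes(sp)

  net <- build_seed_network(ppi, partition, seeds,
                            modules = seed_mods$module)
  hubs <- hub_ranking(net, top_n = 15)
  cat(sprintf("%s: seed network has %d genes / %d interactions; top hub %s (degree %d)%s\n",
              sp, igraph::vcount(net$graph), igraph::ecount(net$graph),
              hubs$gene[1], hubs$degree[1],
              if (any(hubs$is_seed)) " [CCN gene in top 15]" else ""))

  write_seed_network(net, file.path(out_dir, paste0(sp, "_seed_network")))
  write_tsv(hubs, file.path(out_dir, paste0(sp, "_hubs.tsv")))
}
cat("network exports written to", out_dir, "\n")
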