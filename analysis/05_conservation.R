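#!/usr/bin/env Rscript
# Step 5: cross-species conservation — strict one-to-one ortholog
# filtering, shared / human-only / mouse-only classification of the seed
# networks, per-category conservation indices, a three-way ortholog
# overlap with chicken, and the homologous (intersected) CCN network.

suppressPackageStartupMessages(library(ccnnet))

fix_dir <- "results/fixtures"
net_dir <- "results/03_networks"
out_dir <- "results/05_conservation"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

net_genes <- function(sp) {
  g <- igraph::read_graph(file.path(net_dir, paste0(sp, "_seed_network.graphml")),
                          format = "graphml")
  igraph::V(g)$name
}

orth <- read_tsv(file.path(fix_dir, "orthologs.tsv"))
map <- one_to_one_orthologs(orth)
cat(sprintf("one-to-one orthologs retained: %d of %d table rows\n",
            length(map), nrow(orth)))

genes_h <- net_genes("human")
genes_m <- net_genes("mouse")
status <- classify_status(genes_h, genes_m, map)
cat(sprintf("network genes: %d shared pairs, %d human-only, %d mouse-only\n",
            nrow(status$shared), length(status$a_only), length(status$b_only)))

gmt <- read_gmt(file.path(fix_dir, "genesets.gmt"))
rows <- list()
for (term in names(gmt)) {
  cat_a <- intersect(gmt[[term]], genes_h)
  term_b <- map[names(map) %in% gmt[[term]]]
  cat_b <- genes_m[toupper(genes_m) %in% toupper(term_b)]
  if (length(cat_a) == 0 && length(cat_b) == 0) next
  r <- conservation_indices(cat_a, cat_b, map, category = term)
  rows[[term]] <- data.frame(category = term, n_shared = nrow(r$shared),
                             n_human_only = length(r$a_only),
                             n_mouse_only = length(r$b_only),
                             human_centered = r$index_a,
                             mouse_centered = r$index_b,
                             jaccard = r$jaccard)
  cat(sprintf("  %-45s human %.2f mouse %.2f jaccard %.2f\n",
              substr(term, 1, 45), r$index_a, r$index_b, r$jaccard))
}
write_tsv(do.call(rbind, rows), file.path(out_dir, "conservation_by_category.tsv"))

# three-way overlap (chicken genes translated through identity-by-index
# tables is not available on disk; overlap computed on symbols present in
# all three networks via the human-mouse map and case-folded chicken
# symbols, which share the human convention in this fixture)
genes_c <- net_genes("chicken")
ident_c <- setNames(genes_h, genes_h)
tw <- threeway_overlap(genes_h, genes_m, genes_c, map, ident_c)
cat("three-way Venn counts:",
    paste(names(tw$counts), tw$counts, collapse = ", "), "\n")
cat(sprintf("core genes in all three networks: %d\n", length(tw$core)))
jsonlite::write_json(list(counts = as.list(tw$counts), core = tw$core),
                     file.path(out_dir, "venn.json"),
                     auto_unbox = TRUE, pretty = TRUE)

# homologous network: rebuild the two seed networks' graphs and intersect
gh <- igraph::read_graph(file.path(net_dir, "human_seed_network.graphml"),
                         format = "graphml")
gm <- igraph::read_graph(file.path(net_dir, "mouse_seed_network.graphml"),
                         format = "graphml")
wrap <- function(g, sp) {
  structure(list(graph = g,
                 seed_flags = setNames(igraph::V(g)$is_seed > 0,
                                       igraph::V(g)$name),
                 degree = igraph::degree(g),
                 provenance = setNames(vector("list", igraph::vcount(g)),
                                       igraph::V(g)$name)),
            class = "seed_network")
}
hom <- homologous_network(wrap(gh), wrap(gm), map)
cat(sprintf("homologous CCN network: %d genes, %d interactions\n",
            igraph::vcount(hom$graph), igraph::ecount(hom$graph)))
write_seed_network(hom, file.path(out_dir, "homologous_network"))
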