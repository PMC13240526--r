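#!/usr/bin/env Rscript
# Step 6: over-representation analysis of each species' seed network
# against the gene-set collection, BH-FDR control, rollup into the five
# principal functional categories, and an ortholog-status-annotated
# pathway subnetwork for the top enriched term.

suppressPackageStartupMessages(library(ccnnet))

fix_dir <- "results/fixtures"
net_dir <- "results/03_networks"
out_dir <- "results/06_enrichment"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

gmt <- read_gmt(file.path(fix_dir, "genesets.gmt"))
orth <- read_tsv(file.path(fix_dir, "orthologs.tsv"))
map <- one_to_one_orthologs(orth)

load_net <- function(sp) {
  g <- igraph::read_graph(file.path(net_dir, paste0(sp, "_seed_network.graphml")),
                          format = "graphml")
  structure(list(graph = g,
                 seed_flags = setNames(igraph::V(g)$is_seed > 0,
                                       igraph::V(g)$name),
                 degree = igraph::degree(g),
                 provenance = setNames(vector("list", igraph::vcount(g)),
                                       igraph::V(g)$name)),
            class = "seed_network")
}

nets <- lapply(setNames(nm = c("human", "mouse")), load_net)
status <- classify_status(igraph::V(nets$human$graph)$name,
                          igraph::V(nets$mouse$graph)$name, map)

# the gene sets are published in human symbols; for the mouse run they
# are translated through the one-to-one ortholog map first
translate_gmt <- function(gmt, map) {
  lapply(gmt, function(set) unname(map[names(map) %in% set]))
}
gmt_of <- list(human = gmt, mouse = translate_gmt(gmt, map))

for (sp in names(nets)) {
  universe <- read_expression_tsv(
    file.path(fix_dir, paste0(sp, "_expression.tsv"))) |> rownames()
  query <- igraph::V(nets[[sp]]$graph)$name
  enr <- suppressMessages(hypergeom_ora(query, gmt_of[[sp]], universe))
  enr <- categorize_terms(enr)
  sig <- enr[enr$q < 0.05, ]
  cat(sprintf("%s: %d terms tested, %d significant at q < 0.05\n",
              sp, nrow(enr), nrow(sig)))
  for (i in seq_len(min(3, nrow(sig)))) {
    cat(sprintf("  %-45s k=%d/%d q=%.3g [%s]\n",
                substr(sig$term[i], 1, 45), sig$k[i], sig$K[i], sig$q[i],
                sig$category[i]))
  }
  write_tsv(enr, file.path(out_dir, paste0(sp, "_enrichment.tsv")))
  if (nrow(enr) > 0) {
    cc <- as.data.frame(attr(enr, "category_counts"))
    names(cc) <- c("category", "n_terms")
    write_tsv(cc, file.path(out_dir, paste0(sp, "_category_counts.tsv")))
  }
}

# pathway subnetwork for the human top term, ortholog-status colored
enr_h <- read_tsv(file.path(out_dir, "human_enrichment.tsv"))
top_term <- enr_h$term[1]
sub <- pathway_subnetwork(nets$human, gmt[[top_term]], status)
cat(sprintf("pathway subnetwork '%s': %d nodes (%s)\n", top_term,
            igraph::vcount(sub),
            paste(names(table(igraph::V(sub)$status)),
                  table(igraph::V(sub)$status), collapse = ", ")))
igraph::write_graph(sub, file.path(out_dir, "top_pathway_subnetwork.graphml"),
                    format = "graphml")
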