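# Shared fixtures (built once per test run) and independent oracles.
# Oracles are deliberately naive re-implementations used to cross-check
# the package's vectorized code paths.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, builder(), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# the standard bulk fixture: 3 species, 3 modules x 30 genes, 12 samples,
# noise_sd = 0.3
std_bulk <- function() {
  cached("std_bulk", function() {
    generate_bulk_multispecies(n_genes = 120, timepoints = c(1, 4, 7, 10),
                               reps_per_timepoint = 3, n_modules = 3,
                               module_size = 30, trait_effect = 1,
                               noise_sd = 0.3, seed = 42)
  })
}

noiseless_bulk <- function() {
  cached("noiseless_bulk", function() {
    # no background genes: all 90 genes belong to well-separated modules
    generate_bulk_multispecies(n_genes = 90, noise_sd = 0, seed = 42)
  })
}

std_coexpr <- function(species = "human") {
  cached(paste0("std_coexpr_", species), function() {
    b <- std_bulk()[[species]]
    run_coexpr(b$expr, b$truth$day_of_sample, b$truth$seed_genes, beta = 6)
  })
}

std_sc <- function() {
  cached("std_sc", function() generate_singlecell(n_cells = 400, seed = 11))
}

# ---- oracles ----

# adjusted Rand index between two label vectors (contingency form)
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_i * sum_j / n
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}

# depth-1 BFS ball around a seed set
bfs1_oracle <- function(graph, seeds) {
  nodes <- igraph::V(graph)$name
  seeds <- intersect(seeds, nodes)
  ball <- seeds
  for (s in seeds) {
    ball <- union(ball, igraph::neighbors(graph, s)$name)
  }
  sort(ball)
}

# exhaustive best-match size-weighted partition Jaccard
jaccard_oracle <- function(ref, alt) {
  common <- intersect(names(ref), names(alt))
  ref <- ref[common]; alt <- alt[common]
  mods <- setdiff(unique(ref), "grey")
  num <- 0; den <- 0
  for (m in mods) {
    gm <- names(ref)[ref == m]
    js <- vapply(setdiff(unique(alt), "grey"), function(m2) {
      gm2 <- names(alt)[alt == m2]
      length(intersect(gm, gm2)) / length(union(gm, gm2))
    }, numeric(1))
    best <- if (length(js)) max(js) else 0
    num <- num + length(gm) * best
    den <- den + length(gm)
  }
  num / den
}

# exact upper-tail hypergeometric probability by enumeration over the
# overlap count
hyper_oracle <- function(k, K, n, N) {
  total <- choose(N, n)
  sum(vapply(k:min(K, n), function(x) {
    choose(K, x) * choose(N - K, n - x)
  }, numeric(1))) / total
}

# brute-force recovery-curve integration for the AUC activity score
auc_oracle <- function(x, genes, gene_set, top_frac) {
  ord <- order(-x, genes)
  ranked <- genes[ord]
  T_top <- ceiling(top_frac * length(genes))
  set_in <- intersect(gene_set, genes)
  m <- min(length(set_in), T_top)
  hits <- cumsum(ranked %in% set_in)[seq_len(T_top)]
  sum(hits) / sum(pmin(seq_len(T_top), m))
}

# set-algebra recomputation of the three conservation indices
conservation_oracle <- function(genes_a, genes_b, map) {
  mapped <- unname(map[match(toupper(genes_a), toupper(names(map)))])
  shared_a <- genes_a[!is.na(mapped) & toupper(mapped) %in% toupper(genes_b)]
  shared_b <- mapped[!is.na(mapped) & toupper(mapped) %in% toupper(genes_b)]
  ns <- length(shared_a)
  na <- length(setdiff(genes_a, shared_a))
  nb <- length(genes_b[!toupper(genes_b) %in% toupper(shared_b)])
  c(index_a = ns / (ns + na), index_b = ns / (ns + nb),
    jaccard = ns / (ns + na + nb))
}

# random PPI-like igraph for oracle equivalence checks
random_graph <- function(n_nodes, p = 0.15) {
  g <- igraph::sample_gnp(n_nodes, p)
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n_nodes))
  g
}
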