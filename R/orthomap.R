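# Cross-species ortholog handling: strict one-to-one filtering, species
# status classification, conservation indices, three-way overlaps and the
# homologous (intersected) seed network.

#' Filter an ortholog table to strict one-to-one pairs
#'
#' A pair is retained iff its species-A gene appears exactly once among
#' all gene_a entries and its species-B gene exactly once among gene_b
#' entries — the tabular analogue of keeping only reciprocal unique
#' matches in bidirectional homology queries. The result is a bijection.
#'
#' @param table data.frame with columns gene_a, gene_b (homology_type is
#'   ignored; multiplicity decides).
#' @return named character vector: names are species-A symbols, values
#'   species-B symbols (possibly empty).
#' @export
one_to_one_orthologs <- function(table) {
  stopifnot(nrow(table) > 0)
  tab <- table[!duplicated(table[, c("gene_a", "gene_b")]), , drop = FALSE]
  na <- table(tab$gene_a)
  nb <- table(tab$gene_b)
  keep <- na[tab$gene_a] == 1 & nb[tab$gene_b] == 1
  stats::setNames(as.character(tab$gene_b[keep]), tab$gene_a[keep])
}

# case-insensitive lookup of genes in a one-to-one map; returns mapped
# values (species-B display symbols) or NA
map_lookup <- function(map, genes) {
  idx <- match(norm_symbol(genes), norm_symbol(names(map)))
  out <- unname(map[idx])
  names(out) <- genes
  out
}

#' Classify genes as shared, A-only or B-only under a one-to-one map
#'
#' shared = pairs (g, map(g)) with g in genes_a and map(g) in genes_b;
#' a_only = species-A genes without a mapped partner in genes_b; b_only =
#' species-B genes not hit by any shared pair. Symbols are compared
#' case-insensitively.
#'
#' @param genes_a,genes_b character gene sets for the two species.
#' @param map one-to-one map from \code{one_to_one_orthologs}.
#' @return list(shared = data.frame(gene_a, gene_b), a_only, b_only).
#' @export
classify_status <- function(genes_a, genes_b, map) {
  genes_a <- unique(genes_a); genes_b <- unique(genes_b)
  mapped <- map_lookup(map, genes_a)
  hit <- !is.na(mapped) & norm_symbol(mapped) %in% norm_symbol(genes_b)
  shared <- data.frame(gene_a = genes_a[hit],
                       gene_b = unname(mapped[hit]),
                       stringsAsFactors = FALSE)
  a_only <- genes_a[!hit]
  b_only <- genes_b[!(norm_symbol(genes_b) %in% norm_symbol(shared$gene_b))]
  list(shared = shared, a_only = a_only, b_only = b_only)
}

#' Conservation indices for one functional category
#'
#' Three complementary metrics: index_a = |shared| / (|shared| + |a_only|)
#' (species-A-centered), index_b analogous, and the overall Jaccard
#' |shared| / (|shared| + |a_only| + |b_only|). Jaccard never exceeds
#' either centered index.
#'
#' @param category_genes_a,category_genes_b gene sets of the category in
#'   each species.
#' @param map one-to-one ortholog map.
#' @param category optional category label carried into the report.
#' @return list(category, shared, a_only, b_only, index_a, index_b,
#'   jaccard).
#' @export
conservation_indices <- function(category_genes_a, category_genes_b, map,
                                 category = NA_character_) {
  if (length(category_genes_a) == 0 && length(category_genes_b) == 0) {
    stop("undefined index: both category gene sets are empty")
  }
  st <- classify_status(category_genes_a, category_genes_b, map)
  ns <- nrow(st$shared); na <- length(st$a_only); nb <- length(st$b_only)
  list(category = category,
       shared = st$shared, a_only = st$a_only, b_only = st$b_only,
       index_a = if (ns + na > 0) ns / (ns + na) else NA_real_,
       index_b = if (ns + nb > 0) ns / (ns + nb) else NA_real_,
       jaccard = ns / (ns + na + nb))
}

#' Three-way ortholog overlap (7-region Venn)
#'
#' Translates species-B and species-C genes into species-A symbol space
#' with the pairwise one-to-one maps, checks the maps for mutual
#' consistency on their common domains (inconsistent genes are excluded
#' with a message), and places every gene in one of the seven standard
#' Venn regions. The core list is the triple intersection, reported in
#' species-A symbols.
#'
#' @param net_a,net_b,net_c gene sets for the three species.
#' @param map_ab,map_ac one-to-one maps A->B and A->C.
#' @param map_bc optional one-to-one map B->C used to check mutual
#'   consistency: genes where map_bc(map_ab(g)) != map_ac(g) are excluded
#'   from translation with a message.
#' @return list(counts = named 7-region integer vector, core = species-A
#'   symbols in all three sets).
#' @export
threeway_overlap <- function(net_a, net_b, net_c, map_ab, map_ac,
                             map_bc = NULL) {
  if (!is.null(map_bc)) {
    common <- intersect(names(map_ab), names(map_ac))
    via_b <- map_lookup(map_bc, map_ab[common])
    bad <- !is.na(via_b) &
      norm_symbol(via_b) != norm_symbol(unname(map_ac[common]))
    if (any(bad)) {
      message(sprintf("excluding %d gene(s) with inconsistent pairwise maps",
                      sum(bad)))
      map_ab <- map_ab[!names(map_ab) %in% common[bad]]
      map_ac <- map_ac[!names(map_ac) %in% common[bad]]
    }
  }
  a <- unique(norm_symbol(net_a))
  # translate B and C membership into A symbol space
  ab <- stats::setNames(norm_symbol(map_ab), norm_symbol(names(map_ab)))
  ac <- stats::setNames(norm_symbol(map_ac), norm_symbol(names(map_ac)))
  b_as_a <- names(ab)[ab %in% norm_symbol(net_b)]
  c_as_a <- names(ac)[ac %in% norm_symbol(net_c)]
  universe <- unique(c(a, b_as_a, c_as_a))
  in_a <- universe %in% a
  in_b <- universe %in% b_as_a
  in_c <- universe %in% c_as_a
  region <- paste0(ifelse(in_a, "A", ""), ifelse(in_b, "B", ""),
                   ifelse(in_c, "C", ""))
  counts <- stats::setNames(integer(7),
                            c("A", "B", "C", "AB", "AC", "BC", "ABC"))
  tab <- table(region)
  counts[names(tab)[names(tab) %in% names(counts)]] <-
    as.integer(tab[names(tab) %in% names(counts)])
  core_norm <- universe[in_a & in_b & in_c]
  core <- unique(net_a[norm_symbol(net_a) %in% core_norm])
  list(counts = counts, core = sort(core))
}

#' Intersect two species' seed networks into a homologous network
#'
#' Node set = genes present in both networks under the one-to-one map
#' (named by the species-A symbol); an edge is retained when it is present
#' in either species' induced subgraph (union rule, recorded in the
#' \code{in_a}/\code{in_b} edge attributes).
#'
#' @param net_a,net_b \code{seed_network} objects.
#' @param map one-to-one map from species-A to species-B symbols.
#' @return a \code{seed_network} over the shared genes (species-A
#'   symbols).
#' @export
homologous_network <- function(net_a, net_b, map) {
  ga <- igraph::V(net_a$graph)$name
  gb <- igraph::V(net_b$graph)$name
  mapped <- map_lookup(map, ga)
  keep <- !is.na(mapped) & norm_symbol(mapped) %in% norm_symbol(gb)
  shared_a <- ga[keep]
  if (length(shared_a) == 0) {
    warning("homologous network is empty: no shared one-to-one node")
  }
  shared_b <- unname(mapped[keep])
  sub_a <- igraph::induced_subgraph(net_a$graph, shared_a)
  sub_b <- igraph::induced_subgraph(
    net_b$graph, gb[norm_symbol(gb) %in% norm_symbol(shared_b)])
  # translate B edges into A symbol space
  b_to_a <- stats::setNames(shared_a, norm_symbol(shared_b))
  eb <- igraph::as_data_frame(sub_b, what = "edges")
  if (nrow(eb)) {
    eb$from <- unname(b_to_a[norm_symbol(eb$from)])
    eb$to <- unname(b_to_a[norm_symbol(eb$to)])
  }
  ea <- igraph::as_data_frame(sub_a, what = "edges")
  canon <- function(df) {
    if (nrow(df) == 0) return(character(0))
    paste(pmin(df$from, df$to), pmax(df$from, df$to), sep = "\r")
  }
  ka <- canon(ea); kb <- canon(eb)
  all_keys <- unique(c(ka, kb))
  parts <- strsplit(all_keys, "\r", fixed = TRUE)
  edges <- data.frame(
    from = vapply(parts, `[`, character(1), 1),
    to = vapply(parts, `[`, character(1), 2),
    in_a = all_keys %in% ka,
    in_b = all_keys %in% kb,
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = shared_a))
  seeds_a <- names(net_a$seed_flags)[net_a$seed_flags]
  make_seed_network(g, seeds_a)
}
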