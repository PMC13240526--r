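# Seed-centered PPI network construction: STRING-style edge loading,
# module-restricted subgraphs, first-neighbor extraction around seed
# genes, cross-module merging and degree-based hub ranking.

#' Load a STRING-export edge list as a PPI graph
#'
#' Reads a TSV with columns protein1, protein2, combined_score. The score
#' scale is auto-detected: any value > 1 means the 0-1000 STRING dialect
#' and scores are divided by 1000. Edges with normalized score >=
#' \code{threshold} (inclusive) are kept; duplicate pairs are collapsed
#' keeping the maximum score; self-loops are dropped.
#'
#' @param path TSV path.
#' @param threshold confidence threshold in [0, 1] (default 0.4, the
#'   medium-confidence STRING convention).
#' @param id_map optional data.frame(protein, gene) mapping protein IDs to
#'   gene symbols; unmapped rows are dropped with a message.
#' @return an igraph undirected graph with a \code{score} edge attribute.
#' @export
load_string_edges <- function(path, threshold = 0.4, id_map = NULL) {
  if (threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]")
  }
  df <- read_tsv(path)
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% names(df))) {
    stop("format error: expected columns ", paste(need, collapse = ", "))
  }
  score <- as.numeric(df$combined_score)
  if (any(score > 1, na.rm = TRUE)) score <- score / 1000
  df$score <- score
  if (!is.null(id_map)) {
    m1 <- id_map$gene[match(df$protein1, id_map$protein)]
    m2 <- id_map$gene[match(df$protein2, id_map$protein)]
    unmapped <- is.na(m1) | is.na(m2)
    if (any(unmapped)) {
      message(sprintf("dropping %d edge(s) with unmapped protein IDs",
                      sum(unmapped)))
    }
    df$protein1 <- m1
    df$protein2 <- m2
    df <- df[!unmapped, , drop = FALSE]
  }
  df <- df[df$score >= threshold, , drop = FALSE]
  df <- df[df$protein1 != df$protein2, , drop = FALSE]
  # canonical unordered pair, dedup keeping max score
  a <- pmin(df$protein1, df$protein2)
  b <- pmax(df$protein1, df$protein2)
  key <- paste(a, b, sep = "\r")
  ord <- order(key, -df$score)
  df <- data.frame(from = a[ord], to = b[ord], score = df$score[ord],
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(paste(df$from, df$to, sep = "\r")), , drop = FALSE]
  igraph::graph_from_data_frame(df, directed = FALSE)
}

#' Restrict a PPI graph to a module's genes
#'
#' Induced subgraph on the intersection of module genes and graph nodes;
#' module genes absent from the PPI become isolated nodes (kept so
#' downstream seed handling sees them).
#'
#' @param ppi igraph PPI graph.
#' @param module_genes nonempty character vector.
#' @return igraph induced subgraph including isolated module genes.
#' @export
module_subgraph <- function(ppi, module_genes) {
  stopifnot(length(module_genes) > 0)
  present <- intersect(module_genes, igraph::V(ppi)$name)
  if (length(present) == 0) {
    warning("no module gene present in the PPI graph; returning empty graph")
  }
  g <- igraph::induced_subgraph(ppi, present)
  missing <- setdiff(module_genes, present)
  if (length(missing)) {
    g <- igraph::add_vertices(g, length(missing), name = missing)
  }
  g
}

#' Extract the first-neighbor (proximal) network around seed genes
#'
#' Node set = seeds present in the graph plus every direct neighbor of a
#' seed; edge set = all induced edges among those nodes (neighbor-neighbor
#' edges are retained, not just the seed star). Seeds absent from the
#' graph are kept as isolated flagged nodes with a warning, so a species
#' lacking an annotated seed ortholog does not abort the run.
#'
#' @param graph igraph PPI graph (typically a module subgraph).
#' @param seeds nonempty character vector of seed symbols.
#' @param provenance optional module label recorded on every node.
#' @return a \code{seed_network}: list(graph, seed_flags, degree,
#'   provenance).
#' @export
first_neighbors <- function(graph, seeds, provenance = NA_character_) {
  stopifnot(length(seeds) > 0)
  nodes <- igraph::V(graph)$name
  idx <- match(norm_symbol(seeds), norm_symbol(nodes))
  present <- nodes[idx[!is.na(idx)]]
  absent <- seeds[is.na(idx)]
  if (length(present) == 0 && length(absent) == length(seeds)) {
    stop("no seed gene present in the graph")
  }
  nbr <- unique(unlist(lapply(present, function(s) {
    igraph::neighbors(graph, s)$name
  })))
  keep <- unique(c(present, nbr))
  g <- igraph::induced_subgraph(graph, keep)
  if (length(absent)) {
    warning("seed gene(s) absent from graph kept as isolated nodes: ",
            paste(absent, collapse = ", "))
    g <- igraph::add_vertices(g, length(absent), name = absent)
  }
  make_seed_network(g, seeds, provenance)
}

make_seed_network <- function(g, seeds, provenance = NA_character_) {
  nodes <- igraph::V(g)$name
  flags <- norm_symbol(nodes) %in% norm_symbol(seeds)
  prov <- stats::setNames(
    lapply(nodes, function(x) {
      if (is.na(provenance)) character(0) else provenance
    }), nodes)
  structure(list(graph = g,
                 seed_flags = stats::setNames(flags, nodes),
                 degree = igraph::degree(g),
                 provenance = prov),
            class = "seed_network")
}

#' @export
print.seed_network <- function(x, ...) {
  cat(sprintf("seed_network: %d nodes (%d seeds), %d edges\n",
              igraph::vcount(x$graph), sum(x$seed_flags),
              igraph::ecount(x$graph)))
  invisible(x)
}

#' Merge first-neighbor networks across modules
#'
#' Node and edge union; seed flags OR-combined; provenance module labels
#' unioned per node; degrees recomputed on the merged graph. Merging is
#' commutative and associative in node/edge sets, and idempotent.
#'
#' @param nets list of \code{seed_network} objects (empty list gives an
#'   empty network).
#' @return merged \code{seed_network}.
#' @export
merge_networks <- function(nets) {
  if (length(nets) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(structure(list(graph = g, seed_flags = logical(0),
                          degree = numeric(0), provenance = list()),
                     class = "seed_network"))
  }
  edges <- do.call(rbind, lapply(nets, function(n) {
    igraph::as_data_frame(n$graph, what = "edges")
  }))
  nodes <- unique(unlist(lapply(nets, function(n) igraph::V(n$graph)$name)))
  if (!is.null(edges) && nrow(edges) > 0) {
    a <- pmin(edges$from, edges$to)
    b <- pmax(edges$from, edges$to)
    key <- paste(a, b, sep = "\r")
    sc <- if ("score" %in% names(edges)) edges$score else rep(NA_real_, nrow(edges))
    ord <- order(key, -sc)
    edges <- data.frame(from = a[ord], to = b[ord], score = sc[ord],
                        stringsAsFactors = FALSE)
    edges <- edges[!duplicated(paste(edges$from, edges$to, sep = "\r")), ]
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        score = numeric(0), stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  flags <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  prov <- stats::setNames(vector("list", length(nodes)), nodes)
  for (n in nets) {
    nm <- names(n$seed_flags)
    flags[nm] <- flags[nm] | n$seed_flags
    for (x in nm) {
      prov[[x]] <- unique(c(prov[[x]], n$provenance[[x]]))
    }
  }
  structure(list(graph = g, seed_flags = flags,
                 degree = igraph::degree(g), provenance = prov),
            class = "seed_network")
}

#' Rank network hubs by degree
#'
#' Unweighted degree on the (merged) seed network, sorted descending with
#' lexicographic tie-break on the gene symbol.
#'
#' @param net a \code{seed_network}.
#' @param top_n rows to return (default 15, the conventional hub panel).
#' @return data.frame(gene, degree, is_seed), at most \code{top_n} rows.
#' @export
hub_ranking <- function(net, top_n = 15) {
  nodes <- names(net$degree)
  if (length(nodes) == 0) {
    return(data.frame(gene = character(0), degree = integer(0),
                      is_seed = logical(0)))
  }
  ord <- order(-net$degree, nodes)
  take <- ord[seq_len(min(top_n, length(nodes)))]
  data.frame(gene = nodes[take], degree = as.integer(net$degree[take]),
             is_seed = unname(net$seed_flags[nodes[take]]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build the merged seed network from a partition and a PPI graph
#'
#' For each seed-containing module: induce the module subgraph, take the
#' first neighbors of the module's seed genes, then merge across modules.
#'
#' @param ppi igraph PPI graph.
#' @param partition named gene -> module label vector.
#' @param seed_genes seed symbols.
#' @param modules module labels to use; default = every non-grey module
#'   containing a seed.
#' @return merged \code{seed_network}.
#' @export
build_seed_network <- function(ppi, partition, seed_genes, modules = NULL) {
  seed_idx <- match(norm_symbol(seed_genes), norm_symbol(names(partition)))
  if (is.null(modules)) {
    labs <- partition[seed_idx[!is.na(seed_idx)]]
    modules <- setdiff(unique(labs), "grey")
  }
  nets <- list()
  for (m in modules) {
    genes_m <- names(partition)[partition == m]
    sub <- module_subgraph(ppi, genes_m)
    seeds_m <- seed_genes[norm_symbol(seed_genes) %in% norm_symbol(genes_m)]
    if (length(seeds_m) == 0) next
    nets[[m]] <- first_neighbors(sub, seeds_m, provenance = m)
  }
  merge_networks(nets)
}

#' Export a seed network to edge-list TSV and GraphML
#'
#' @param net a \code{seed_network}.
#' @param prefix output path prefix; writes \code{<prefix>_edges.tsv} and
#'   \code{<prefix>.graphml}.
#' @param ortholog_status optional named vector gene -> status annotation.
#' @return invisible character vector of written paths.
#' @export
write_seed_network <- function(net, prefix, ortholog_status = NULL) {
  g <- net$graph
  igraph::V(g)$is_seed <- unname(net$seed_flags[igraph::V(g)$name])
  igraph::V(g)$degree <- unname(net$degree[igraph::V(g)$name])
  igraph::V(g)$provenance <- vapply(igraph::V(g)$name, function(x) {
    paste(net$provenance[[x]], collapse = ";")
  }, character(1))
  if (!is.null(ortholog_status)) {
    igraph::V(g)$ortholog_status <-
      unname(ortholog_status[igraph::V(g)$name])
  }
  edges <- igraph::as_data_frame(g, what = "edges")
  tsv <- paste0(prefix, "_edges.tsv")
  gml <- paste0(prefix, ".graphml")
  write_tsv(edges, tsv)
  igraph::write_graph(g, gml, format = "graphml")
  invisible(c(tsv, gml))
}
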