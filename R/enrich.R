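# Over-representation analysis against GMT collections with BH-FDR
# control, rollup into five principal functional categories, and
# ortholog-status-annotated pathway subnetworks.

#' Hypergeometric over-representation analysis
#'
#' Per term: p = P(X >= k), X hypergeometric with population N (universe),
#' K successes (term genes in the universe) and n draws (query genes in
#' the universe). Terms with no query overlap (k = 0) are omitted.
#' Benjamini-Hochberg adjustment is applied across all tested terms.
#'
#' @param query character gene set; genes outside \code{universe} are
#'   dropped with a message.
#' @param collection named list of term gene vectors (see
#'   \code{read_gmt}).
#' @param universe character background gene set (>= 2 genes).
#' @return data.frame(term, k, K, n, N, p, q), sorted by p.
#' @export
hypergeom_ora <- function(query, collection, universe) {
  universe <- unique(universe)
  if (length(universe) < 2) stop("universe must contain at least 2 genes")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    message(sprintf("dropping %d query gene(s) outside the universe",
                    length(outside)))
    query <- intersect(query, universe)
  }
  if (length(query) == 0) {
    warning("empty query after universe filtering")
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), stringsAsFactors = FALSE))
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection), function(term) {
    term_genes <- intersect(unique(collection[[term]]), universe)
    K <- length(term_genes)
    k <- length(intersect(term_genes, query))
    if (k == 0) return(NULL)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out[order(out$p, out$term), , drop = FALSE]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' q_(i) = min_{j >= i} p_(j) m / j on the ascending-sorted p-values,
#' clipped at 1 and returned in input order. Output never falls below the
#' raw p-value.
#'
#' @param pvals numeric vector, every element in (0, 1].
#' @return q-values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals <= 0 | pvals > 1 | is.na(pvals))) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Default keyword rules mapping terms to the five principal categories
#'
#' Ordered pattern -> category rules (first match wins) covering the five
#' principal functional categories used to roll up enriched terms:
#' ECM/structural constituents, cell fate & development, cytoskeleton,
#' microenvironmental response, and signaling networks.
#'
#' @return data.frame(pattern, category) in precedence order.
#' @export
default_category_rules <- function() {
  data.frame(
    pattern = c("extracellular matrix|collagen|ECM|structural|proteoglycan|basement membrane",
                "differentiation|development|cell fate|morphogenesis|chondro|osteo|ossification|cartilage",
                "cytoskelet|actin|microtubule|filament",
                "hypoxia|oxidative|inflammat|mechanical|stress|microenvironment|wound",
                "signaling|signal transduction|pathway|kinase|SMAD|TGF|BMP|FGF|IGF|Hippo|Wnt|integrin"),
    category = c("ECM and structural tissue constituent",
                 "cell fate, differentiation and development",
                 "cytoskeleton",
                 "microenvironmental response",
                 "signaling networks"),
    stringsAsFactors = FALSE)
}

#' Assign enriched terms to principal functional categories
#'
#' First matching rule wins (rules are in precedence order); terms
#' matching no rule are labeled "unclassified".
#'
#' @param results data.frame with a \code{term} column (e.g. from
#'   \code{hypergeom_ora}).
#' @param rules data.frame(pattern, category); patterns are
#'   case-insensitive regular expressions.
#' @return \code{results} with a \code{category} column added, plus a
#'   \code{"category_counts"} attribute.
#' @export
categorize_terms <- function(results, rules = default_category_rules()) {
  if (!is.data.frame(rules) || !all(c("pattern", "category") %in% names(rules))) {
    stop("config error: rules need 'pattern' and 'category' columns")
  }
  assign_one <- function(term) {
    for (i in seq_len(nrow(rules))) {
      if (grepl(rules$pattern[i], term, ignore.case = TRUE)) {
        return(rules$category[i])
      }
    }
    "unclassified"
  }
  results$category <- vapply(results$term, assign_one, character(1),
                             USE.NAMES = FALSE)
  attr(results, "category_counts") <- table(results$category)
  results
}

#' Extract an ortholog-status-annotated pathway subnetwork
#'
#' Induced subgraph of the seed network on the term's genes plus the seed
#' genes, with each node annotated shared / a_only / b_only (from a
#' \code{classify_status} result) and seeds flagged.
#'
#' @param net a \code{seed_network}.
#' @param term_genes character gene set of the pathway/term.
#' @param status output of \code{classify_status} for the two species'
#'   networks.
#' @return igraph graph with \code{status} and \code{is_seed} vertex
#'   attributes.
#' @export
pathway_subnetwork <- function(net, term_genes, status) {
  nodes <- igraph::V(net$graph)$name
  seeds <- names(net$seed_flags)[net$seed_flags]
  keep <- nodes[norm_symbol(nodes) %in% norm_symbol(c(term_genes, seeds))]
  if (length(setdiff(keep, seeds)) == 0) {
    warning("pathway has no overlap with the network beyond the seeds")
  }
  g <- igraph::induced_subgraph(net$graph, keep)
  nm <- igraph::V(g)$name
  node_status <- rep("unknown", length(nm))
  node_status[norm_symbol(nm) %in% norm_symbol(status$shared$gene_a)] <- "shared"
  node_status[norm_symbol(nm) %in% norm_symbol(status$a_only)] <- "a_only"
  node_status[norm_symbol(nm) %in% norm_symbol(status$b_only)] <- "b_only"
  igraph::V(g)$status <- node_status
  igraph::V(g)$is_seed <- norm_symbol(nm) %in% norm_symbol(seeds)
  g
}
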