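# Orchestration: config validation, per-species end-to-end runs
# (co-expression -> seed network -> stability -> enrichment) and
# cross-species conservation runs, all driven by one master seed.

#' Derive a deterministic per-stage seed from the master seed
#'
#' One master seed in the config is split into per-stage seeds so a
#' single knob reproduces the whole run; the derived value stays below
#' 2^31 - 1.
#'
#' @param master integer master seed.
#' @param k stage index.
#' @return integer seed.
#' @export
derive_seed <- function(master, k) {
  as.integer((as.numeric(master) %% 1000003) * 1009 + 7919 * k) %% 2147483647L
}

#' Read an expression TSV (gene column + one column per sample)
#'
#' @param path TSV with a \code{gene} first column.
#' @return genes x samples numeric matrix.
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

pipeline_defaults <- function() {
  list(beta = 6, min_module_size = 30, cut_height_frac = 0.98,
       string_threshold = 0.4, n_iter = 10, boot_frac = 0.8,
       leaveout_frac = 0.1, alpha_trait = 0.05, q_threshold = 0.05,
       hub_top_n = 15, seed = 1)
}

#' Validate and resolve a pipeline config file
#'
#' Parses a YAML config, checks that every referenced path exists and
#' every analyzed species has a nonempty seed-gene list, fills parameter
#' defaults (STRING threshold 0.4, bootstrap 10 x 0.8, leave-out 0.1,
#' enrichment q < 0.05, hub top 15), and reports every problem at once.
#'
#' @param path YAML config path.
#' @return resolved config list with a \code{params} element.
#' @export
validate_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  problems <- character(0)
  if (is.null(cfg$species) || length(cfg$species) == 0) {
    problems <- c(problems, "config lists no species")
  }
  for (sp in names(cfg$species)) {
    entry <- cfg$species[[sp]]
    for (key in c("expression", "samples", "string_edges")) {
      p <- entry[[key]]
      if (is.null(p)) {
        problems <- c(problems, sprintf("%s: missing '%s' path", sp, key))
      } else if (!file.exists(p)) {
        problems <- c(problems, sprintf("%s: path does not exist: %s", sp, p))
      }
    }
    if (is.null(entry$seeds) || length(entry$seeds) == 0) {
      problems <- c(problems, sprintf("%s: empty seed-gene list", sp))
    }
  }
  for (key in c("orthologs", "genesets")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      problems <- c(problems, sprintf("path does not exist: %s", cfg[[key]]))
    }
  }
  if (is.null(cfg$outdir)) problems <- c(problems, "missing 'outdir'")
  if (length(problems)) {
    stop("config validation failed:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  cfg$params <- utils::modifyList(pipeline_defaults(),
                                  if (is.null(cfg$params)) list() else cfg$params)
  cfg
}

#' Run the full per-species analysis
#'
#' Executes co-expression module detection, seed-network construction,
#' bootstrap + leave-out stability and enrichment in order, writing all
#' artifacts under \code{outdir/<species>}. Identical config + seed give
#' identical outputs.
#'
#' @param config resolved config from \code{validate_config}.
#' @param species species name present in the config.
#' @return invisible list bundle: coexpr result, seed network, hub table,
#'   stability report, enrichment table, output paths.
#' @export
run_species <- function(config, species) {
  if (!species %in% names(config$species)) {
    stop("species not present in config: ", species)
  }
  p <- config$params
  entry <- config$species[[species]]
  outdir <- file.path(config$outdir, species)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  expr <- read_expression_tsv(entry$expression)
  meta <- read_tsv(entry$samples)
  day <- stats::setNames(meta$day, meta$sample)
  ppi <- load_string_edges(entry$string_edges, threshold = p$string_threshold)

  cx <- run_coexpr(expr, day, entry$seeds, beta = p$beta,
                   min_module_size = p$min_module_size,
                   cut_height_frac = p$cut_height_frac,
                   alpha = p$alpha_trait)
  net <- build_seed_network(ppi, cx$partition, entry$seeds,
                            modules = cx$seed_selection$modules)
  hubs <- hub_ranking(net, top_n = p$hub_top_n)

  boot <- bootstrap_stability(expr, day, entry$seeds,
                              params = list(beta = p$beta,
                                            min_module_size = p$min_module_size,
                                            cut_height_frac = p$cut_height_frac),
                              n_iter = p$n_iter, frac = p$boot_frac,
                              seed = derive_seed(p$seed, 1))
  lo <- tryCatch(
    leaveout_retention(expr, day, entry$seeds, ppi,
                       params = list(beta = p$beta,
                                     min_module_size = p$min_module_size,
                                     cut_height_frac = p$cut_height_frac),
                       frac_out = p$leaveout_frac,
                       seed = derive_seed(p$seed, 2)),
    error = function(e) list(retention_rate = NA_real_,
                             error = conditionMessage(e)))

  enrichment <- data.frame()
  if (!is.null(config$genesets)) {
    gmt <- read_gmt(config$genesets)
    query <- igraph::V(net$graph)$name
    universe <- rownames(expr)
    enrichment <- hypergeom_ora(query, gmt, universe)
    enrichment <- categorize_terms(enrichment)
  }

  write_tsv(data.frame(gene = names(cx$partition), module = cx$partition,
                       stringsAsFactors = FALSE),
            file.path(outdir, "partition.tsv"))
  if (nrow(cx$eigengenes) > 0) {
    write_tsv(data.frame(module = rownames(cx$eigengenes), cx$eigengenes,
                         check.names = FALSE),
              file.path(outdir, "eigengenes.tsv"))
  }
  write_tsv(cx$trait_cor, file.path(outdir, "trait_correlation.tsv"))
  write_seed_network(net, file.path(outdir, "seed_network"))
  write_tsv(hubs, file.path(outdir, "hubs.tsv"))
  stab <- boot
  stab$retention_rate <- lo$retention_rate
  write_stability_report(stab, file.path(outdir, "stability.json"))
  if (nrow(enrichment) > 0) {
    write_tsv(enrichment, file.path(outdir, "enrichment.tsv"))
    cc <- as.data.frame(attr(enrichment, "category_counts"))
    names(cc) <- c("category", "n_terms")
    write_tsv(cc, file.path(outdir, "category_counts.tsv"))
  }
  invisible(list(coexpr = cx, network = net, hubs = hubs,
                 bootstrap = boot, leaveout = lo,
                 enrichment = enrichment, outdir = outdir))
}

#' Run the cross-species conservation analysis
#'
#' Applies strict one-to-one ortholog filtering, classifies the two
#' species' seed-network genes as shared / A-only / B-only, computes
#' conservation indices per functional category (the category gene sets
#' are the GMT term genes intersected with each species' network, the
#' species-B side translated through the ortholog map), and intersects
#' the networks into a homologous network.
#'
#' @param bundle_a,bundle_b outputs of \code{run_species}.
#' @param ortholog_table data.frame(gene_a, gene_b, homology_type).
#' @param gmt named list of gene sets in species-A symbols (optional).
#' @param outdir output directory (optional; artifacts written when
#'   given).
#' @return list(map, status, reports, homologous, venn = NULL).
#' @export
run_crossspecies <- function(bundle_a, bundle_b, ortholog_table,
                             gmt = NULL, outdir = NULL) {
  map <- one_to_one_orthologs(ortholog_table)
  genes_a <- igraph::V(bundle_a$network$graph)$name
  genes_b <- igraph::V(bundle_b$network$graph)$name
  status <- classify_status(genes_a, genes_b, map)
  reports <- list()
  if (!is.null(gmt)) {
    for (term in names(gmt)) {
      cat_a <- intersect(norm_symbol(gmt[[term]]), norm_symbol(genes_a))
      cat_a <- genes_a[norm_symbol(genes_a) %in% cat_a]
      term_b <- map_lookup(map, gmt[[term]])
      term_b <- term_b[!is.na(term_b)]
      cat_b <- genes_b[norm_symbol(genes_b) %in% norm_symbol(term_b)]
      if (length(cat_a) == 0 && length(cat_b) == 0) next
      reports[[term]] <- conservation_indices(cat_a, cat_b, map,
                                              category = term)
    }
  }
  hom <- homologous_network(bundle_a$network, bundle_b$network, map)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (length(reports)) {
      df <- do.call(rbind, lapply(reports, function(r) {
        data.frame(category = r$category, n_shared = nrow(r$shared),
                   n_a_only = length(r$a_only), n_b_only = length(r$b_only),
                   index_a = r$index_a, index_b = r$index_b,
                   jaccard = r$jaccard, stringsAsFactors = FALSE)
      }))
      write_tsv(df, file.path(outdir, "conservation.tsv"))
    }
    status_vec <- stats::setNames(rep("a_only", length(genes_a)), genes_a)
    status_vec[status$shared$gene_a] <- "shared"
    write_seed_network(hom, file.path(outdir, "homologous_network"),
                       ortholog_status = status_vec)
  }
  list(map = map, status = status, reports = reports, homologous = hom)
}
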