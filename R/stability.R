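# Resampling stability of module detection and of the seed network:
# bootstrap-style subsample Jaccard and single leave-out retention.

#' Best-match, size-weighted partition Jaccard
#'
#' For each non-grey reference module M the best Jaccard overlap with any
#' alternative module is taken, J(M) = max_M' |M n M'| / |M u M'|; the
#' returned index is the size-weighted mean of J(M) over reference
#' modules. Grey (unassigned) genes are excluded from both partitions so
#' unassigned genes cannot dominate the unions.
#'
#' @param ref,alt named gene -> module label vectors over the same gene
#'   universe.
#' @return a real in [0, 1].
#' @export
partition_jaccard <- function(ref, alt) {
  common <- intersect(names(ref), names(alt))
  ref <- ref[common]; alt <- alt[common]
  ref_mods <- setdiff(unique(ref), "grey")
  alt_mods <- setdiff(unique(alt), "grey")
  if (length(ref_mods) == 0) {
    stop("undefined metric: reference partition has no non-grey module")
  }
  wsum <- 0; wtot <- 0
  for (m in ref_mods) {
    gm <- names(ref)[ref == m]
    best <- 0
    for (m2 in alt_mods) {
      gm2 <- names(alt)[alt == m2]
      j <- length(intersect(gm, gm2)) / length(union(gm, gm2))
      if (j > best) best <- j
    }
    wsum <- wsum + length(gm) * best
    wtot <- wtot + length(gm)
  }
  wsum / wtot
}

#' Subsample-bootstrap stability of module detection
#'
#' Runs the co-expression stage on the full data (the reference), then
#' \code{n_iter} times on a uniform random subset of
#' \code{floor(frac * n_samples)} samples drawn without replacement, and
#' records the partition Jaccard of each rerun against the reference.
#' Deterministic given \code{seed}.
#'
#' @param expr genes x samples matrix.
#' @param day_of_sample named numeric day per sample.
#' @param seed_genes seed symbols (passed through to the stage).
#' @param params list of co-expression parameters (beta,
#'   min_module_size, cut_height_frac); see \code{run_coexpr}.
#' @param n_iter resampling iterations (default 10).
#' @param frac sample fraction per iteration (default 0.8).
#' @param seed integer RNG seed.
#' @return a stability report: list(per_iteration_jaccard, mean_jaccard,
#'   n_iterations, sample_fraction, seed, metric, resampling).
#' @export
bootstrap_stability <- function(expr, day_of_sample, seed_genes,
                                params = list(), n_iter = 10, frac = 0.8,
                                seed = 1) {
  n_sub <- floor(frac * ncol(expr))
  if (n_sub < 3) stop("insufficient data: subsample would have < 3 samples")
  p <- utils::modifyList(list(beta = 6, min_module_size = 30,
                              cut_height_frac = 0.98), params)
  ref <- run_coexpr(expr, day_of_sample, seed_genes, beta = p$beta,
                    min_module_size = p$min_module_size,
                    cut_height_frac = p$cut_height_frac)
  js <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      cols <- sort(sample(ncol(expr), n_sub))
      sub <- expr[, cols, drop = FALSE]
      alt <- suppressWarnings(
        run_coexpr(sub, day_of_sample[colnames(sub)], seed_genes,
                   beta = p$beta, min_module_size = p$min_module_size,
                   cut_height_frac = p$cut_height_frac))
      partition_jaccard(ref$partition, alt$partition)
    }, numeric(1))
  })
  list(per_iteration_jaccard = js,
       mean_jaccard = mean(js),
       n_iterations = n_iter,
       sample_fraction = frac,
       seed = seed,
       metric = "best-match size-weighted Jaccard vs full-data reference, grey excluded",
       resampling = "without replacement",
       reference = ref)
}

#' Single leave-out retention of the seed network
#'
#' Removes a uniform random \code{floor(frac_out * n_samples)} samples
#' once, reruns the co-expression + seed-network stages end to end, and
#' reports the fraction of the full-run seed-network genes still present
#' in the reduced-run network, plus the lost/gained gene lists.
#'
#' @param expr genes x samples matrix.
#' @param day_of_sample named numeric day per sample.
#' @param seed_genes seed symbols.
#' @param ppi igraph PPI graph.
#' @param params co-expression parameter list (see
#'   \code{bootstrap_stability}).
#' @param frac_out fraction of samples removed (default 0.1).
#' @param seed integer RNG seed.
#' @return list(retention_rate, retained, lost, gained, n_removed,
#'   reference_genes).
#' @export
leaveout_retention <- function(expr, day_of_sample, seed_genes, ppi,
                               params = list(), frac_out = 0.1, seed = 1) {
  n_out <- floor(frac_out * ncol(expr))
  if (n_out < 1) stop("frac_out removes no sample")
  p <- utils::modifyList(list(beta = 6, min_module_size = 30,
                              cut_height_frac = 0.98), params)
  run_net <- function(e) {
    cx <- suppressWarnings(
      run_coexpr(e, day_of_sample[colnames(e)], seed_genes, beta = p$beta,
                 min_module_size = p$min_module_size,
                 cut_height_frac = p$cut_height_frac))
    suppressWarnings(build_seed_network(ppi, cx$partition, seed_genes))
  }
  full_net <- run_net(expr)
  full_genes <- igraph::V(full_net$graph)$name
  if (length(full_genes) == 0) {
    stop("undefined retention: full-run seed network is empty")
  }
  reduced <- with_seed(seed, {
    drop <- sample(ncol(expr), n_out)
    expr[, -drop, drop = FALSE]
  })
  red_net <- run_net(reduced)
  red_genes <- igraph::V(red_net$graph)$name
  retained <- intersect(full_genes, red_genes)
  list(retention_rate = length(retained) / length(full_genes),
       retained = retained,
       lost = setdiff(full_genes, red_genes),
       gained = setdiff(red_genes, full_genes),
       n_removed = n_out,
       reference_genes = full_genes)
}

#' Write a stability report to JSON (plus a retained/lost gene TSV)
#'
#' @param report output of \code{bootstrap_stability} (the
#'   \code{reference} element is replaced by a summary) optionally merged
#'   with \code{leaveout_retention} fields.
#' @param path JSON output path.
#' @return \code{path}, invisibly.
#' @export
write_stability_report <- function(report, path) {
  report$reference <- NULL
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
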