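# Single-cell stage: QC filtering, depth normalization, per-cell gene-set
# activity (recovery-curve AUC and a rank-sum alternative), population
# proportions over time, simplified ligand-receptor strength, and the
# bulk-side trajectory summaries (percent-of-reference-day, PCA).

#' Standard single-cell QC threshold profiles
#'
#' \code{hipsc}: min 200 / max 7000 detected genes, mito fraction <= 5%,
#' genes kept when detected in >= 3 cells. \code{embryonic_limb}: min 200
#' / max 6000 detected genes, mito fraction <= 10%, no min-cell gene
#' filter.
#'
#' @param name profile name.
#' @return list(min_genes, max_genes, max_mito, min_cells_per_gene).
#' @export
qc_profiles <- function(name = c("hipsc", "embryonic_limb")) {
  switch(match.arg(name),
         hipsc = list(min_genes = 200, max_genes = 7000, max_mito = 0.05,
                      min_cells_per_gene = 3),
         embryonic_limb = list(min_genes = 200, max_genes = 6000,
                               max_mito = 0.10, min_cells_per_gene = 1))
}

#' Quality-control filtering of a cell x gene count matrix
#'
#' Removes cells with fewer than \code{min_genes} or more than
#' \code{max_genes} detected genes, or with a mitochondrial count
#' fraction strictly greater than \code{max_mito} (a cell exactly at the
#' boundary is kept); then removes genes detected in fewer than
#' \code{min_cells_per_gene} of the remaining cells. Cells are filtered
#' before genes, so the gene filter sees only surviving cells. The
#' operation is idempotent.
#'
#' @param counts cell x gene matrix (dense or sparse), nonnegative
#'   integers.
#' @param cell_meta data.frame with a \code{cell} column matching
#'   rownames.
#' @param mito_genes character vector of mitochondrially-tagged genes.
#' @param min_genes,max_genes detected-gene bounds (cells kept when
#'   min_genes <= detected <= max_genes).
#' @param max_mito maximum mitochondrial count fraction (strict > removes).
#' @param min_cells_per_gene minimum cells a gene must be detected in.
#' @return list(counts, cell_meta, mito_genes, report) where report
#'   counts removals per rule.
#' @export
qc_filter <- function(counts, cell_meta, mito_genes,
                      min_genes = 200, max_genes = 7000, max_mito = 0.05,
                      min_cells_per_gene = 3) {
  stopifnot(max_genes > min_genes, min_genes > 0, max_mito >= 0)
  detected <- Matrix::rowSums(counts > 0)
  total <- Matrix::rowSums(counts)
  mito_cols <- intersect(mito_genes, colnames(counts))
  mito_frac <- if (length(mito_cols)) {
    Matrix::rowSums(counts[, mito_cols, drop = FALSE]) / pmax(total, 1)
  } else {
    rep(0, nrow(counts))
  }
  low <- detected < min_genes
  high <- detected > max_genes
  mito_bad <- mito_frac > max_mito
  keep_cells <- !(low | high | mito_bad)
  if (!any(keep_cells)) {
    dominant <- names(which.max(c(min_genes = sum(low), max_genes = sum(high),
                                  max_mito = sum(mito_bad))))
    stop("all cells removed by QC; dominant rule: ", dominant)
  }
  counts <- counts[keep_cells, , drop = FALSE]
  cells_detected <- Matrix::colSums(counts > 0)
  keep_genes <- cells_detected >= min_cells_per_gene
  report <- list(
    removed_min_genes = sum(low),
    removed_max_genes = sum(high & !low),
    removed_max_mito = sum(mito_bad & !low & !high),
    removed_cells = sum(!keep_cells),
    removed_genes = sum(!keep_genes),
    cells_kept = sum(keep_cells),
    genes_kept = sum(keep_genes),
    thresholds = list(min_genes = min_genes, max_genes = max_genes,
                      max_mito = max_mito,
                      min_cells_per_gene = min_cells_per_gene))
  list(counts = counts[, keep_genes, drop = FALSE],
       cell_meta = cell_meta[cell_meta$cell %in% rownames(counts), ,
                             drop = FALSE],
       mito_genes = intersect(mito_genes, colnames(counts)[keep_genes]),
       report = report)
}

#' Median-depth normalization and log transform
#'
#' Scales each cell's counts to the median total count across cells, then
#' applies log(1 + x). Cells with zero total are removed with a warning.
#'
#' @param counts cell x gene matrix.
#' @return cell x gene dense numeric matrix of normalized values.
#' @export
normalize_log <- function(counts) {
  total <- Matrix::rowSums(counts)
  if (any(total == 0)) {
    warning(sprintf("removing %d zero-total cell(s)", sum(total == 0)))
    counts <- counts[total > 0, , drop = FALSE]
    total <- total[total > 0]
  }
  med <- stats::median(total)
  scaled <- as.matrix(counts) * (med / total)
  log1p(scaled)
}

# deterministic per-cell gene ranking: decreasing expression, ties broken
# lexicographically by gene symbol (a strict total order)
rank_genes_desc <- function(x, genes) {
  ord <- order(-x, genes)
  pos <- integer(length(x))
  pos[ord] <- seq_along(x)
  stats::setNames(pos, genes)
}

#' Recovery-curve AUC gene-set activity per cell
#'
#' For each cell, genes are ranked by decreasing normalized expression
#' (ties broken lexicographically for determinism). With T =
#' ceiling(top_frac x n_genes), the score is the cumulative count of
#' gene-set members within the top t ranks, summed over t = 1..T, divided
#' by the maximum achievable sum (all countable set genes at the very
#' top), so the score lies in [0, 1] and equals 1 in the best case.
#'
#' @param cm_norm cell x gene normalized matrix.
#' @param gene_set character gene set; its intersection with the gene
#'   universe must be nonempty.
#' @param top_frac fraction of top-ranked genes integrated over (default
#'   0.05, the usual recovery-curve convention).
#' @return list(score = named per-cell numeric in [0,1], method = "auc",
#'   top_frac, gene_set).
#' @export
aucell_score <- function(cm_norm, gene_set, top_frac = 0.05) {
  stopifnot(top_frac > 0, top_frac <= 1)
  genes <- colnames(cm_norm)
  set_in <- intersect(unique(gene_set), genes)
  if (length(set_in) == 0) {
    stop("gene set has no overlap with the gene universe")
  }
  n_genes <- length(genes)
  T_top <- ceiling(top_frac * n_genes)
  m <- min(length(set_in), T_top)
  max_sum <- sum(pmin(seq_len(T_top), m))
  score <- apply(cm_norm, 1, function(x) {
    pos <- rank_genes_desc(x, genes)[set_in]
    pos <- pos[pos <= T_top]
    sum(T_top - pos + 1) / max_sum
  })
  list(score = score, method = "auc", top_frac = top_frac,
       gene_set = paste(deparse(substitute(gene_set)), collapse = ""))
}

#' Rank-sum (Mann-Whitney-U based) gene-set activity per cell
#'
#' Per cell, ranks (decreasing expression, average ties) are clipped at
#' \code{max_rank}; U = sum of set-gene ranks - m(m+1)/2 and the score is
#' 1 - U / (m x max_rank), clipped to [0, 1]. All set genes at the top
#' ranks give exactly 1.
#'
#' @param cm_norm cell x gene normalized matrix.
#' @param gene_set character gene set.
#' @param max_rank rank clip (default 1500).
#' @return list(score, method = "rank_sum", max_rank, gene_set).
#' @export
rank_sum_score <- function(cm_norm, gene_set, max_rank = 1500) {
  genes <- colnames(cm_norm)
  set_in <- intersect(unique(gene_set), genes)
  if (length(set_in) == 0) {
    stop("gene set has no overlap with the gene universe")
  }
  m <- length(set_in)
  score <- apply(cm_norm, 1, function(x) {
    r <- rank(-x, ties.method = "average")
    names(r) <- genes
    rr <- pmin(r[set_in], max_rank)
    U <- sum(rr) - m * (m + 1) / 2
    min(max(1 - U / (m * max_rank), 0), 1)
  })
  list(score = score, method = "rank_sum", max_rank = max_rank,
       gene_set = paste(deparse(substitute(gene_set)), collapse = ""))
}

#' Population proportions per time point
#'
#' @param cell_meta data.frame with \code{time_point} and
#'   \code{population} columns; every cell must be labeled.
#' @return data.frame time_point x population of proportions; each row
#'   sums to 1, zero-count populations reported as 0.
#' @export
population_proportions <- function(cell_meta) {
  if (nrow(cell_meta) == 0) stop("empty cell metadata")
  if (any(is.na(cell_meta$time_point)) || any(is.na(cell_meta$population))) {
    stop("every cell must carry time_point and population labels")
  }
  tab <- table(cell_meta$time_point, cell_meta$population)
  prop <- sweep(tab, 1, rowSums(tab), "/")
  df <- as.data.frame.matrix(prop)
  df <- cbind(data.frame(time_point = rownames(df), stringsAsFactors = FALSE),
              df)
  rownames(df) <- NULL
  df
}

#' Simplified sender -> receiver ligand-receptor strength
#'
#' strength(s, r, (L, R)) = mean normalized expression of the ligand L in
#' sender population s times the mean normalized expression of the
#' receptor R in receiver population r — a declared simplification of
#' probabilistic ligand-activity frameworks that preserves the ranking of
#' strongly co-expressed pairs.
#'
#' @param cm_norm cell x gene normalized matrix.
#' @param cell_meta data.frame(cell, population, ...).
#' @param lr_pairs data.frame(ligand, receptor); pairs referencing
#'   unknown genes are skipped with a message.
#' @param senders,receivers population label sets.
#' @return data.frame(sender, receiver, ligand, receptor, strength),
#'   sorted by decreasing strength.
#' @export
lr_strength <- function(cm_norm, cell_meta, lr_pairs, senders, receivers) {
  pops <- unique(cell_meta$population)
  if (!all(senders %in% pops) || !all(receivers %in% pops)) {
    stop("sender or receiver population absent from metadata")
  }
  mean_in_pop <- function(gene, pop) {
    cells <- cell_meta$cell[cell_meta$population == pop]
    cells <- intersect(cells, rownames(cm_norm))
    if (length(cells) == 0) stop("empty population: ", pop)
    mean(cm_norm[cells, gene])
  }
  rows <- list()
  for (i in seq_len(nrow(lr_pairs))) {
    L <- lr_pairs$ligand[i]; R <- lr_pairs$receptor[i]
    if (!(L %in% colnames(cm_norm)) || !(R %in% colnames(cm_norm))) {
      message(sprintf("skipping pair %s-%s: gene not in matrix", L, R))
      next
    }
    for (s in senders) for (r in receivers) {
      rows[[length(rows) + 1L]] <- data.frame(
        sender = s, receiver = r, ligand = L, receptor = R,
        strength = mean_in_pop(L, s) * mean_in_pop(R, r),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sender = character(0), receiver = character(0),
               ligand = character(0), receptor = character(0),
               strength = numeric(0))
  out[order(-out$strength), , drop = FALSE]
}

#' Express per-day gene means as a percentage of a reference day
#'
#' Per gene and day: 100 x (mean across replicates at that day) / (mean
#' at \code{ref_day}). Genes whose reference mean is at or below machine
#' tolerance are flagged and excluded from the table.
#'
#' @param expr genes x samples matrix.
#' @param day_of_sample named numeric day per sample.
#' @param ref_day reference day (must be present).
#' @return list(table = gene x day matrix of percentages, flagged =
#'   excluded gene symbols).
#' @export
percent_of_reference <- function(expr, day_of_sample, ref_day) {
  day <- day_of_sample[colnames(expr)]
  if (!ref_day %in% day) stop("ref_day not present in sample metadata")
  days <- sort(unique(day))
  means <- sapply(days, function(d) {
    rowMeans(expr[, day == d, drop = FALSE])
  })
  colnames(means) <- as.character(days)
  ref <- means[, as.character(ref_day)]
  flagged <- rownames(expr)[abs(ref) <= .Machine$double.eps^0.5]
  keep <- setdiff(rownames(expr), flagged)
  tab <- 100 * means[keep, , drop = FALSE] / ref[keep]
  list(table = tab, flagged = flagged)
}

#' PCA of samples from a gene x sample expression matrix
#'
#' Genes are centered (and unit-scaled when their variance is positive),
#' then a singular value decomposition gives sample scores for every
#' component; variance explained sums to 1. Component signs are fixed so
#' the loading of the lexicographically first gene is nonnegative, making
#' results reproducible across platforms.
#'
#' @param expr genes x samples matrix (>= 2 samples).
#' @return list(scores = sample x component matrix, variance_explained,
#'   loadings = gene x component matrix).
#' @export
pca_scores <- function(expr) {
  if (ncol(expr) < 2) stop("PCA needs at least 2 samples")
  v <- apply(expr, 1, stats::var)
  z <- expr - rowMeans(expr)
  z[v > 0, ] <- z[v > 0, , drop = FALSE] / sqrt(v[v > 0])
  sv <- svd(t(z))  # samples x genes
  ncomp <- sum(sv$d > .Machine$double.eps^0.5 * sv$d[1])
  scores <- sv$u[, seq_len(ncomp), drop = FALSE] %*%
    diag(sv$d[seq_len(ncomp)], ncomp)
  loadings <- sv$v[, seq_len(ncomp), drop = FALSE]
  rownames(loadings) <- rownames(expr)
  rownames(scores) <- colnames(expr)
  first_gene <- sort(rownames(expr))[1]
  for (j in seq_len(ncomp)) {
    if (loadings[first_gene, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- paste0("PC", seq_len(ncomp))
  colnames(loadings) <- colnames(scores)
  ve <- sv$d^2 / sum(sv$d^2)
  list(scores = scores, variance_explained = ve[seq_len(ncomp)],
       loadings = loadings)
}
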