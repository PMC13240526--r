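# Signed-hybrid weighted co-expression analysis: adjacency, topological
# overlap, static-height module detection, module eigengenes and
# module-trait correlation.

# Standard WGCNA module color sequence; modules are named by decreasing
# size so the largest module is always "turquoise".
wgcna_colors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta")

#' Drop zero-variance genes from an expression matrix
#'
#' Correlation is undefined for constant genes; they are removed with a
#' warning naming the count.
#'
#' @param expr genes x samples matrix.
#' @return expression matrix without constant rows.
#' @export
drop_constant_genes <- function(expr) {
  v <- apply(expr, 1, stats::var)
  const <- v < .Machine$double.eps
  if (any(const)) {
    warning(sprintf("dropping %d constant-expression gene(s)", sum(const)))
    expr <- expr[!const, , drop = FALSE]
  }
  expr
}

#' Signed-hybrid co-expression adjacency
#'
#' a_ij = cor(i, j)^beta when the Pearson correlation is positive, 0
#' otherwise; a_ii = 1. Negative correlations are zeroed rather than
#' folded in, so anti-correlated genes never share a module.
#'
#' @param expr genes x samples matrix (>= 3 samples; constant genes are
#'   dropped with a warning).
#' @param beta positive integer soft-thresholding power.
#' @return symmetric gene x gene adjacency in [0, 1] with unit diagonal.
#' @export
adjacency_signed_hybrid <- function(expr, beta) {
  stopifnot(is.numeric(beta), length(beta) == 1, beta >= 1)
  if (ncol(expr) < 3) stop("insufficient data: need at least 3 samples")
  expr <- drop_constant_genes(expr)
  r <- stats::cor(t(expr))
  a <- ifelse(r > 0, r^beta, 0)
  diag(a) <- 1
  a
}

#' Choose the soft-thresholding power by the scale-free topology criterion
#'
#' For each candidate power the signed-hybrid adjacency is formed, node
#' connectivity k_i = sum_j a_ij - 1 binned (>= 5 occupied bins), and the
#' scale-free model fit R^2 taken from a linear regression of log10
#' frequency on log10 mean connectivity per bin. The smallest candidate
#' reaching \code{r2_target} is returned; if none qualifies the declared
#' fallback is used and flagged.
#'
#' @param expr genes x samples matrix.
#' @param candidate_powers integer candidates (default 1:20).
#' @param r2_target required fit, in (0, 1].
#' @param fallback power returned when no candidate qualifies (default 9).
#' @param n_bins connectivity bins for the fit (default 10).
#' @return list(power, fallback_used, fit_table) where fit_table has one
#'   row per candidate with its R^2.
#' @export
pick_soft_power <- function(expr, candidate_powers = 1:20, r2_target = 0.8,
                            fallback = 9, n_bins = 10) {
  if (length(candidate_powers) == 0) stop("candidate_powers must be nonempty")
  if (r2_target <= 0 || r2_target > 1) {
    stop("r2_target must lie in (0, 1]")
  }
  expr <- drop_constant_genes(expr)
  if (nrow(expr) == 0) stop("all genes constant")
  fits <- vapply(candidate_powers, function(b) {
    a <- adjacency_signed_hybrid(expr, b)
    k <- rowSums(a) - 1
    scale_free_r2(k, n_bins = n_bins)
  }, numeric(1))
  fit_table <- data.frame(power = candidate_powers, r2 = fits)
  ok <- which(fits >= r2_target)
  if (length(ok)) {
    list(power = candidate_powers[min(ok)], fallback_used = FALSE,
         fit_table = fit_table)
  } else {
    list(power = fallback, fallback_used = TRUE, fit_table = fit_table)
  }
}

# R^2 of log10(frequency) ~ log10(mean connectivity) over connectivity
# bins; NA-safe, returns 0 when fewer than 5 occupied bins.
scale_free_r2 <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < 5) return(0)
  brk <- unique(stats::quantile(k, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(brk) < 6) brk <- unique(seq(min(k), max(k), length.out = n_bins + 1))
  bin <- cut(k, breaks = brk, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  kmean <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0 & kmean > 0
  if (sum(keep) < 5) return(0)
  # near-perfect fits are routine on clean synthetic data; the summary
  # warning about them carries no information here
  suppressWarnings({
    fit <- stats::lm(log10(freq[keep]) ~ log10(kmean[keep]))
    summary(fit)$r.squared
  })
}

#' Topological overlap similarity
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) with the
#' sum over u distinct from i and j and k_i = sum_u a_iu (u != i);
#' TOM_ii = 1. Genes score as similar when they share neighbors even if
#' their direct adjacency is modest.
#'
#' @param adj symmetric adjacency in [0, 1] with unit diagonal.
#' @return symmetric TOM matrix in [0, 1] with unit diagonal.
#' @export
tom_similarity <- function(adj) {
  if (!isSymmetric(unname(adj), tol = 1e-10)) {
    stop("adjacency must be symmetric")
  }
  if (any(adj < -1e-12) || any(adj > 1 + 1e-12)) {
    stop("adjacency values must lie in [0, 1]")
  }
  a <- adj
  diag(a) <- 1
  k <- rowSums(a) - 1
  # (A^2)_ij with unit diagonal counts a_ii a_ij + a_ij a_jj = 2 a_ij extra
  shared <- a %*% a - 2 * a
  num <- shared + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom <- pmin(pmax(tom, 0), 1)
  dimnames(tom) <- dimnames(adj)
  (tom + t(tom)) / 2
}

#' Detect co-expression modules by static tree cut on 1 - TOM
#'
#' Average-linkage hierarchical clustering on the TOM dissimilarity,
#' cut at \code{cut_height_frac} of the maximum merge height. Clusters
#' smaller than \code{min_module_size} are relabeled "grey" (unassigned);
#' surviving modules are named by decreasing size with the conventional
#' WGCNA color sequence, so the largest module is "turquoise".
#'
#' @param tom TOM similarity matrix (see \code{tom_similarity}).
#' @param min_module_size smallest retained module (default 30).
#' @param cut_height_frac cut height as a fraction of the maximum merge
#'   height, in (0, 1] (default 0.98).
#' @return named character vector gene -> module color ("grey" =
#'   unassigned).
#' @export
detect_modules <- function(tom, min_module_size = 30, cut_height_frac = 0.98) {
  stopifnot(cut_height_frac > 0, cut_height_frac <= 1, min_module_size >= 2)
  genes <- rownames(tom)
  if (nrow(tom) < min_module_size) {
    warning("fewer genes than min_module_size; all genes unassigned (grey)")
    return(stats::setNames(rep("grey", nrow(tom)), genes))
  }
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  h <- cut_height_frac * max(hc$height)
  cl <- stats::cutree(hc, h = h)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- rep("grey", length(cl))
  if (length(keep)) {
    ord <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(ord)) {
      labels[cl == as.integer(ord[i])] <-
        wgcna_colors[((i - 1L) %% length(wgcna_colors)) + 1L]
    }
  }
  stats::setNames(labels, genes)
}

#' Module eigengenes and variance explained
#'
#' The eigengene of a module is the first right singular vector of its
#' per-gene z-scored expression submatrix (the module's first principal
#' component across samples), sign-oriented so it correlates nonnegatively
#' with the module's mean expression profile, making results independent
#' of gene-row ordering. Variance explained is the first squared singular
#' value over the total.
#'
#' @param expr genes x samples matrix.
#' @param partition named gene -> module label vector covering
#'   \code{expr}'s genes; "grey" genes are skipped.
#' @return list(eigengenes = module x sample matrix with unit-norm rows,
#'   variance_explained = named numeric).
#' @export
module_eigengenes <- function(expr, partition) {
  stopifnot(all(rownames(expr) %in% names(partition)))
  mods <- setdiff(unique(partition[rownames(expr)]), "grey")
  me <- matrix(NA_real_, nrow = length(mods), ncol = ncol(expr),
               dimnames = list(mods, colnames(expr)))
  ve <- stats::setNames(numeric(length(mods)), mods)
  drop <- character(0)
  for (m in mods) {
    genes <- rownames(expr)[partition[rownames(expr)] == m]
    sub <- expr[genes, , drop = FALSE]
    z <- t(scale(t(sub)))
    z <- z[stats::complete.cases(z), , drop = FALSE]
    if (nrow(z) == 0) {
      warning(sprintf("module %s empty after z-scoring; skipped", m))
      drop <- c(drop, m)
      next
    }
    sv <- svd(z)
    v1 <- sv$v[, 1]
    if (stats::sd(colMeans(sub)) > 0 &&
        stats::cor(v1, colMeans(sub)) < 0) {
      v1 <- -v1
    }
    me[m, ] <- v1 / sqrt(sum(v1^2))
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  if (length(drop)) {
    me <- me[!rownames(me) %in% drop, , drop = FALSE]
    ve <- ve[setdiff(names(ve), drop)]
  }
  list(eigengenes = me, variance_explained = ve)
}

#' Correlate module eigengenes with the culture-day trait
#'
#' Pearson correlation of each eigengene with numeric day; two-sided
#' p-value from the t distribution on n - 2 degrees of freedom.
#'
#' @param eigengenes module x sample matrix.
#' @param day_of_sample named numeric day per sample (or a numeric vector
#'   aligned with the eigengene columns).
#' @return data.frame(module, cor, p).
#' @export
module_trait_correlation <- function(eigengenes, day_of_sample) {
  if (!is.null(names(day_of_sample)) && !is.null(colnames(eigengenes))) {
    day_of_sample <- day_of_sample[colnames(eigengenes)]
  }
  if (ncol(eigengenes) < 3) stop("insufficient data: need at least 3 samples")
  if (stats::sd(day_of_sample) == 0) stop("constant trait: day is degenerate")
  out <- lapply(rownames(eigengenes), function(m) {
    ct <- stats::cor.test(eigengenes[m, ], day_of_sample, method = "pearson")
    data.frame(module = m, cor = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Select seed-containing, trait-significant modules
#'
#' Returns the non-grey modules that contain at least one seed gene and
#' whose eigengene-day correlation is significant at \code{alpha}. Seeds
#' landing in grey (unassigned) are reported separately.
#'
#' @param partition named gene -> module label vector.
#' @param seed_genes character vector of seed symbols (matched
#'   case-insensitively).
#' @param trait_cor data.frame from \code{module_trait_correlation}.
#' @param alpha significance level (default 0.05).
#' @return list(modules, unassigned_seeds, missing_seeds).
#' @export
seed_modules <- function(partition, seed_genes, trait_cor, alpha = 0.05) {
  stopifnot(length(seed_genes) > 0)
  idx <- match(norm_symbol(seed_genes), norm_symbol(names(partition)))
  missing <- seed_genes[is.na(idx)]
  if (all(is.na(idx))) {
    stop("no seed gene present in the expression data: ",
         paste(missing, collapse = ", "))
  }
  present <- seed_genes[!is.na(idx)]
  labels <- partition[idx[!is.na(idx)]]
  unassigned <- present[labels == "grey"]
  cand <- setdiff(unique(labels), "grey")
  sig <- trait_cor$module[trait_cor$p < alpha]
  list(modules = intersect(cand, sig),
       unassigned_seeds = unassigned,
       missing_seeds = missing)
}

#' Run the full co-expression stage on one species
#'
#' Convenience wrapper: drop constants, adjacency at a fixed (or
#' criterion-chosen) power, TOM, module detection, eigengenes, trait
#' correlation and seed-module selection.
#'
#' @param expr genes x samples matrix.
#' @param day_of_sample named numeric day per sample.
#' @param seed_genes seed symbols.
#' @param beta soft power; when NULL it is chosen by
#'   \code{pick_soft_power}.
#' @param min_module_size,cut_height_frac,alpha see the stage functions.
#' @return list(partition, eigengenes, variance_explained, trait_cor,
#'   seed_selection, beta).
#' @export
run_coexpr <- function(expr, day_of_sample, seed_genes, beta = 6,
                       min_module_size = 30, cut_height_frac = 0.98,
                       alpha = 0.05) {
  expr <- drop_constant_genes(expr)
  if (is.null(beta)) {
    beta <- pick_soft_power(expr)$power
  }
  adj <- adjacency_signed_hybrid(expr, beta)
  tom <- tom_similarity(adj)
  partition <- detect_modules(tom, min_module_size, cut_height_frac)
  me <- module_eigengenes(expr, partition)
  tc <- if (nrow(me$eigengenes) > 0) {
    module_trait_correlation(me$eigengenes, day_of_sample)
  } else {
    data.frame(module = character(0), cor = numeric(0), p = numeric(0))
  }
  sel <- tryCatch(seed_modules(partition, seed_genes, tc, alpha),
                  error = function(e) list(modules = character(0),
                                           unassigned_seeds = character(0),
                                           missing_seeds = seed_genes))
  list(partition = partition, eigengenes = me$eigengenes,
       variance_explained = me$variance_explained, trait_cor = tc,
       seed_selection = sel, beta = beta)
}
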