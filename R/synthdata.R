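# Synthetic multi-species fixtures with planted ground truth.
#
# Every generator is a pure function of its parameters and seed (RNG state
# is restored on exit), so downstream stages can be tested against known
# truth without external data.

#' Default seed-gene symbols per species
#'
#' The matricellular CCN family (CCN1-CCN6) written in each species'
#' symbol convention: uppercase for human and chicken, capitalized for
#' mouse. Chicken lacks an annotated CCN6 ortholog, so only five symbols
#' are returned for it.
#'
#' @param species one of "human", "mouse", "chicken".
#' @param n number of seed genes (default 2: the dominant CCN1/CCN2 pair).
#' @return character vector of seed-gene symbols.
#' @export
default_seed_genes <- function(species, n = 2) {
  base <- paste0("CCN", seq_len(if (identical(species, "chicken")) min(n, 5) else n))
  if (identical(species, "mouse")) {
    base <- paste0("Ccn", seq_len(length(base)))
  }
  base
}

species_symbol <- function(species, idx) {
  sym <- sprintf("GENE%04d", idx)
  if (identical(species, "mouse")) {
    sym <- sprintf("Gene%04d", idx)
  }
  sym
}

# Day-dependent latent profiles: orthogonal polynomial contrasts over the
# day vector, cycled with sign flips when there are more modules than
# available degrees. Module 1 gets the linear (monotone "maturation")
# profile so the seed module correlates with culture day.
module_latents <- function(day, n_modules) {
  deg <- min(n_modules, length(unique(day)) - 1L)
  if (deg < 1L) {
    stop("at least two distinct timepoints are required (trait degeneracy)")
  }
  P <- stats::poly(day, degree = deg)
  out <- matrix(0, nrow = length(day), ncol = n_modules)
  for (m in seq_len(n_modules)) {
    col <- ((m - 1L) %% deg) + 1L
    flip <- if (((m - 1L) %/% deg) %% 2L == 1L) -1 else 1
    out[, m] <- flip * P[, col] * sqrt(length(day))  # ~unit-sd latent
  }
  out
}

#' Generate multi-species bulk expression time courses with planted modules
#'
#' Builds one normalized gene-by-sample expression matrix per species.
#' Genes in the same planted module share a day-dependent latent profile
#' (gene value = loading x trait_effect x latent + Gaussian noise); genes
#' outside any module are pure noise. Designated seed genes are placed in
#' the largest planted module (module 1), mirroring the dominant module
#' that typically hosts CCN1/CCN2.
#'
#' @param n_genes total genes per species.
#' @param timepoints numeric culture days (>= 2 distinct values).
#' @param reps_per_timepoint biological replicates per day.
#' @param n_modules number of planted co-expression modules.
#' @param module_size genes per planted module.
#' @param trait_effect scale of the day-dependent signal (0 = pure noise).
#' @param noise_sd Gaussian noise sd added to module genes (>= 0).
#' @param species character vector of species labels.
#' @param n_seeds number of CCN-like seed genes per species.
#' @param seed integer RNG seed; identical seed gives byte-identical output.
#' @return list with one element per species, each a list of
#'   \code{expr} (genes x samples matrix), \code{sample_meta}
#'   (sample, species, day, replicate) and \code{truth} (a BulkTruth:
#'   \code{module_of_gene} with "none" for background genes,
#'   \code{seed_genes}, \code{day_of_sample}, \code{noise_sd}).
#' @export
generate_bulk_multispecies <- function(n_genes = 120,
                                       timepoints = c(1, 4, 7, 10),
                                       reps_per_timepoint = 3,
                                       n_modules = 3,
                                       module_size = 30,
                                       trait_effect = 1,
                                       noise_sd = 0.3,
                                       species = c("human", "mouse", "chicken"),
                                       n_seeds = 2,
                                       seed = 1) {
  stopifnot(n_genes >= 1, n_modules >= 1, module_size >= 1,
            reps_per_timepoint >= 1, noise_sd >= 0)
  if (n_modules * module_size > n_genes) {
    stop("module capacity exceeded: n_modules * module_size > n_genes")
  }
  if (length(unique(timepoints)) < 2) {
    stop("at least two distinct timepoints are required (trait degeneracy)")
  }
  with_seed(seed, {
    day <- rep(sort(timepoints), each = reps_per_timepoint)
    n_samples <- length(day)
    latents <- module_latents(day, n_modules)
    out <- list()
    for (sp_i in seq_along(species)) {
      sp <- species[[sp_i]]
      genes <- species_symbol(sp, seq_len(n_genes))
      seeds_sp <- default_seed_genes(sp, n_seeds)
      # seeds live in module 1 (the designated largest/dominant module)
      genes[seq_along(seeds_sp)] <- seeds_sp
      module_of_gene <- rep("none", n_genes)
      for (m in seq_len(n_modules)) {
        idx <- ((m - 1L) * module_size + 1L):(m * module_size)
        module_of_gene[idx] <- paste0("M", m)
      }
      names(module_of_gene) <- genes
      expr <- matrix(0, nrow = n_genes, ncol = n_samples,
                     dimnames = list(genes, sprintf("%s_d%g_r%d", sp, day,
                                                    rep(seq_len(reps_per_timepoint),
                                                        length(timepoints)))))
      for (g in seq_len(n_genes)) {
        m <- module_of_gene[g]
        if (m == "none") {
          expr[g, ] <- stats::rnorm(n_samples, sd = 1)
        } else {
          mi <- as.integer(sub("^M", "", m))
          loading <- stats::runif(1, 0.8, 1.2)
          expr[g, ] <- loading * trait_effect * latents[, mi] +
            stats::rnorm(n_samples, sd = noise_sd)
        }
      }
      sample_meta <- data.frame(sample = colnames(expr), species = sp,
                                day = day,
                                replicate = rep(seq_len(reps_per_timepoint),
                                                length(timepoints)),
                                stringsAsFactors = FALSE)
      day_of_sample <- stats::setNames(day, colnames(expr))
      out[[sp]] <- list(
        expr = expr,
        sample_meta = sample_meta,
        truth = list(module_of_gene = module_of_gene,
                     seed_genes = seeds_sp,
                     day_of_sample = day_of_sample,
                     noise_sd = noise_sd)
      )
    }
    out
  })
}

#' Generate a synthetic PPI graph from planted module labels
#'
#' Edge presence is Bernoulli: probability \code{p_within} for gene pairs
#' in the same planted module and \code{p_between} otherwise; confidence
#' scores are drawn uniformly in \code{score_range}. The graph is
#' undirected with no self-loops or duplicate edges.
#'
#' @param truth a BulkTruth (needs \code{module_of_gene}).
#' @param p_within,p_between edge probabilities, \code{p_within > p_between}.
#' @param score_range length-2 numeric in [0,1], lo <= hi.
#' @param seed integer RNG seed.
#' @return an igraph graph with a \code{score} edge attribute.
#' @export
generate_ppi <- function(truth, p_within = 0.8, p_between = 0.05,
                         score_range = c(0.4, 1), seed = 1) {
  if (any(c(p_within, p_between) < 0) || any(c(p_within, p_between) > 1)) {
    stop("edge probabilities must lie in [0, 1]")
  }
  if (p_within < p_between) stop("p_within must be at least p_between")
  if (length(score_range) != 2 || score_range[1] > score_range[2] ||
      score_range[1] < 0 || score_range[2] > 1) {
    stop("score_range must be [lo, hi] within [0, 1]")
  }
  mod <- truth$module_of_gene
  genes <- names(mod)
  n <- length(genes)
  with_seed(seed, {
    from <- character(0); to <- character(0); score <- numeric(0)
    if (n >= 2) {
      pairs <- utils::combn(n, 2)
      same <- mod[pairs[1, ]] == mod[pairs[2, ]] & mod[pairs[1, ]] != "none"
      p <- ifelse(same, p_within, p_between)
      keep <- stats::runif(ncol(pairs)) < p
      from <- genes[pairs[1, keep]]
      to <- genes[pairs[2, keep]]
      score <- stats::runif(sum(keep), score_range[1], score_range[2])
    }
    g <- igraph::graph_from_data_frame(
      data.frame(from = from, to = to, score = score,
                 stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = data.frame(name = genes, stringsAsFactors = FALSE))
    g
  })
}

#' Generate an ortholog table and GMT gene-set collection for two species
#'
#' Genes of the two species are aligned by generation index. Each index is
#' assigned a homology type: \code{one2one} (a single reciprocal pair),
#' \code{one2many} (the species-A gene maps to two species-B genes), or
#' \code{none} (species-specific, no row emitted). Seed genes and any
#' caller-designated core genes are forced one-to-one so cross-species
#' fixtures have a known conserved core. Each emitted GMT set overlaps one
#' planted module by construction, padded with random background genes.
#'
#' @param truth_a,truth_b BulkTruth objects from
#'   \code{generate_bulk_multispecies} for the two species.
#' @param frac_one2one,frac_species_only type fractions; their sum must be
#'   <= 1, the remainder becomes one2many.
#' @param n_sets number of GMT sets (named after functional themes so the
#'   default category rules match them).
#' @param core_genes indices (into the generation order) always forced
#'   one2one, in addition to the seed genes.
#' @param seed integer RNG seed.
#' @return list with \code{orthologs} (data.frame gene_a, gene_b,
#'   homology_type), \code{gmt} (named list of species-A gene vectors) and
#'   \code{type_of_index} (the planted per-index homology type).
#' @export
generate_orthologs_and_genesets <- function(truth_a, truth_b,
                                            frac_one2one = 0.7,
                                            frac_species_only = 0.15,
                                            n_sets = 5,
                                            core_genes = integer(0),
                                            seed = 1) {
  if (frac_one2one < 0 || frac_species_only < 0 ||
      frac_one2one + frac_species_only > 1) {
    stop("homology-type fractions must be nonnegative and sum to at most 1")
  }
  genes_a <- names(truth_a$module_of_gene)
  genes_b <- names(truth_b$module_of_gene)
  n <- min(length(genes_a), length(genes_b))
  with_seed(seed, {
    n_one <- round(frac_one2one * n)
    n_only <- round(frac_species_only * n)
    n_many <- n - n_one - n_only
    type <- sample(rep(c("one2one", "none", "one2many"),
                       c(n_one, n_only, n_many)))
    forced <- unique(c(which(genes_a %in% truth_a$seed_genes),
                       which(genes_b %in% truth_b$seed_genes),
                       core_genes))
    forced <- forced[forced <= n]
    if (frac_one2one > 0) type[forced] <- "one2one"
    rows <- list()
    for (i in seq_len(n)) {
      if (type[i] == "one2one") {
        rows[[length(rows) + 1L]] <-
          data.frame(gene_a = genes_a[i], gene_b = genes_b[i],
                     homology_type = "one2one", stringsAsFactors = FALSE)
      } else if (type[i] == "one2many") {
        # extra target drawn outside the one2one indices so planted
        # one-to-one pairs survive the strict downstream filter
        pool <- setdiff(which(type != "one2one"), i)
        if (length(pool) == 0) pool <- setdiff(seq_len(n), i)
        j <- if (length(pool) == 1) pool else sample(pool, 1)
        rows[[length(rows) + 1L]] <-
          data.frame(gene_a = rep(genes_a[i], 2),
                     gene_b = c(genes_b[i], genes_b[j]),
                     homology_type = "one2many", stringsAsFactors = FALSE)
      }
    }
    orthologs <- if (length(rows)) do.call(rbind, rows) else
      data.frame(gene_a = character(0), gene_b = character(0),
                 homology_type = character(0), stringsAsFactors = FALSE)
    orthologs <- orthologs[!duplicated(orthologs[, c("gene_a", "gene_b")]), ]

    themes <- c("extracellular matrix organization",
                "cartilage development and cell differentiation",
                "cytoskeleton organization",
                "response to hypoxia",
                "TGF-beta signaling pathway",
                "collagen biosynthesis",
                "integrin-mediated adhesion")
    mods <- sort(unique(truth_a$module_of_gene[truth_a$module_of_gene != "none"]))
    background <- genes_a[truth_a$module_of_gene == "none"]
    gmt <- list()
    for (s in seq_len(n_sets)) {
      m <- mods[((s - 1L) %% length(mods)) + 1L]
      members <- genes_a[truth_a$module_of_gene == m]
      take <- sample(members, max(3, round(0.6 * length(members))))
      pad <- if (length(background)) {
        sample(background, min(length(background), 5))
      } else character(0)
      set <- unique(c(take, pad))
      attr(set, "description") <- paste("synthetic set over planted module", m)
      gmt[[themes[((s - 1L) %% length(themes)) + 1L]]] <- set
    }
    list(orthologs = orthologs, gmt = gmt, type_of_index = type)
  })
}

#' Generate a synthetic single-cell count matrix with planted activity
#'
#' Negative-binomial counts (fixed dispersion) for cells spread across
#' discrete populations and time points. One population (the first) has
#' the planted gene set's mean expression shifted up by
#' \code{activity_shift} on the log scale. A ligand/receptor pair is
#' planted high in sender (mesenchyme-like, first half of populations) and
#' receiver (second half) populations respectively. Mitochondrially-tagged
#' genes ("MT-...") and deliberate QC violators (one cell below the
#' min-genes rule, one above the max-genes rule, one above the
#' mitochondrial-fraction rule) are always present so quality-control
#' filters are exercised.
#'
#' @param n_cells number of cells.
#' @param populations >= 2 population labels; the first carries the
#'   planted activity elevation.
#' @param timepoints time-point labels.
#' @param n_genes total genes (including mito and planted genes).
#' @param active_set_size size of the planted high-activity gene set.
#' @param activity_shift log-scale mean shift of the active set in the
#'   active population (0 = no planted contrast).
#' @param n_mito number of mitochondrially-tagged genes.
#' @param qc list(min_genes, max_genes, max_mito) the fixture's QC
#'   thresholds; violators are planted just outside them.
#' @param planted_lr c(ligand=, receptor=) symbols planted high in
#'   senders/receivers.
#' @param seed integer RNG seed.
#' @return list with \code{counts} (sparse cell x gene dgCMatrix),
#'   \code{cell_meta} (cell, time_point, population) and \code{truth}
#'   (an ScTruth: population/time maps, active set, mito genes, planted
#'   violator cell ids, qc thresholds).
#' @export
generate_singlecell <- function(n_cells = 400,
                                populations = c("mesenchyme_1", "mesenchyme_2",
                                                "chondrocytes_1", "chondrocytes_2"),
                                timepoints = c("D1", "D7", "D14"),
                                n_genes = 300,
                                active_set_size = 20,
                                activity_shift = 2,
                                n_mito = 10,
                                qc = list(min_genes = 50, max_genes = 270,
                                          max_mito = 0.05),
                                planted_lr = c(ligand = "CCN1",
                                               receptor = "ITGB1"),
                                seed = 1) {
  if (length(populations) < 2) {
    stop("at least two populations are required for a planted contrast")
  }
  stopifnot(active_set_size >= 1, n_genes > n_mito + active_set_size + 2)
  with_seed(seed, {
    active_genes <- sprintf("ACT%03d", seq_len(active_set_size))
    mito_genes <- sprintf("MT-G%02d", seq_len(n_mito))
    other <- sprintf("BG%04d", seq_len(n_genes - active_set_size - n_mito - 2))
    genes <- c(planted_lr[["ligand"]], planted_lr[["receptor"]],
               active_genes, mito_genes, other)
    population <- sample(populations, n_cells, replace = TRUE)
    time_point <- sample(timepoints, n_cells, replace = TRUE)
    cells <- sprintf("cell%04d", seq_len(n_cells))

    base_mu <- stats::rlnorm(length(genes), meanlog = -0.5, sdlog = 1)
    names(base_mu) <- genes
    # mito baseline gives ~2-3% mitochondrial fraction in typical cells,
    # comfortably inside the QC bound; one violator is planted explicitly
    base_mu[mito_genes] <- 0.7
    depth <- stats::rlnorm(n_cells, meanlog = 0, sdlog = 0.3)

    senders <- populations[seq_len(ceiling(length(populations) / 2))]
    receivers <- setdiff(populations, senders)
    counts <- matrix(0L, nrow = n_cells, ncol = length(genes),
                     dimnames = list(cells, genes))
    for (ci in seq_len(n_cells)) {
      mu <- base_mu * depth[ci]
      if (population[ci] == populations[1]) {
        mu[active_genes] <- mu[active_genes] * exp(activity_shift)
      }
      if (population[ci] %in% senders) {
        mu[planted_lr[["ligand"]]] <- mu[planted_lr[["ligand"]]] * 8
      }
      if (length(receivers) && population[ci] %in% receivers) {
        mu[planted_lr[["receptor"]]] <- mu[planted_lr[["receptor"]]] * 8
      }
      counts[ci, ] <- stats::rnbinom(length(genes), mu = mu, size = 2)
    }

    # planted QC violators (never in the active population so the planted
    # contrast survives filtering)
    ok <- which(population != populations[1])
    viol <- ok[seq_len(3)]
    low <- viol[1]; high <- viol[2]; mito_v <- viol[3]
    keep_idx <- sample(length(genes), max(1, qc$min_genes - 10))
    row <- integer(length(genes)); row[keep_idx] <- 1L
    counts[low, ] <- row
    counts[high, ] <- pmax(counts[high, ], 1L)  # detected in every gene
    counts[mito_v, mito_genes] <-
      as.integer(ceiling(2 * qc$max_mito * sum(counts[mito_v, ]) /
                           max(1, n_mito) + 5))

    cell_meta <- data.frame(cell = cells, time_point = time_point,
                            population = population,
                            stringsAsFactors = FALSE)
    truth <- list(
      population_of_cell = stats::setNames(population, cells),
      time_of_cell = stats::setNames(time_point, cells),
      active_set = list(name = "planted_activity_set", genes = active_genes),
      active_population = populations[1],
      mito_genes = mito_genes,
      planted_lr = planted_lr,
      senders = senders, receivers = receivers,
      qc = qc,
      violators = list(low_genes = cells[low], high_genes = cells[high],
                       high_mito = cells[mito_v])
    )
    list(counts = Matrix::Matrix(counts, sparse = TRUE),
         cell_meta = cell_meta, truth = truth)
  })
}

#' Write a complete synthetic fixture bundle to a directory
#'
#' Emits every input the pipeline reads, in the on-disk formats it reads
#' them in: per-species expression + sample-metadata TSVs, a STRING-style
#' edge TSV per species (0-1000 score dialect), an ortholog TSV, a GMT
#' collection, and a MatrixMarket single-cell bundle (matrix.mtx,
#' genes.tsv, cells.tsv).
#'
#' @param dir output directory (created if needed).
#' @param bulk result of \code{generate_bulk_multispecies}.
#' @param ppi named list of igraph PPI graphs per species.
#' @param ortho result of \code{generate_orthologs_and_genesets}.
#' @param sc result of \code{generate_singlecell}.
#' @return \code{dir}, invisibly.
#' @export
write_fixture_bundle <- function(dir, bulk, ppi = NULL, ortho = NULL,
                                 sc = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in names(bulk)) {
    expr <- bulk[[sp]]$expr
    df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write_tsv(df, file.path(dir, paste0(sp, "_expression.tsv")))
    write_tsv(bulk[[sp]]$sample_meta, file.path(dir, paste0(sp, "_samples.tsv")))
  }
  if (!is.null(ppi)) {
    for (sp in names(ppi)) {
      el <- igraph::as_data_frame(ppi[[sp]], what = "edges")
      out <- data.frame(protein1 = el$from, protein2 = el$to,
                        combined_score = round(el$score * 1000),
                        stringsAsFactors = FALSE)
      write_tsv(out, file.path(dir, paste0(sp, "_string_edges.tsv")))
    }
  }
  if (!is.null(ortho)) {
    write_tsv(ortho$orthologs, file.path(dir, "orthologs.tsv"))
    write_gmt(ortho$gmt, file.path(dir, "genesets.gmt"))
  }
  if (!is.null(sc)) {
    Matrix::writeMM(sc$counts, file.path(dir, "matrix.mtx"))
    writeLines(colnames(sc$counts), file.path(dir, "genes.tsv"))
    write_tsv(sc$cell_meta, file.path(dir, "cells.tsv"))
  }
  invisible(dir)
}
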