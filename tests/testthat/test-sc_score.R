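# Single-cell QC, normalization, activity scores, proportions,
# ligand-receptor strength, percent-of-reference and PCA.

toy_counts <- function(m) {
  rn <- sprintf("c%02d", seq_len(nrow(m)))
  cn <- sprintf("g%02d", seq_len(ncol(m)))
  dimnames(m) <- list(rn, cn)
  m
}

test_that("QC boundaries follow the strict-removal reading", {
  n_genes <- 300
  counts <- matrix(0L, nrow = 4, ncol = n_genes,
                   dimnames = list(paste0("c", 1:4), paste0("g", 1:n_genes)))
  mito <- paste0("g", 1:10)
  counts[1, seq_len(150)] <- 1L               # 150 detected: below min
  counts[2, seq_len(200)] <- 1L               # exactly 200: kept
  counts[3, 11:200] <- 1L; counts[3, 1] <- 10L  # mito 10/200 = exactly 5%
  counts[4, 11:200] <- 1L; counts[4, 1] <- 11L  # mito 11/201: just above 5%
  meta <- data.frame(cell = rownames(counts))
  q <- qc_filter(counts, meta, mito, min_genes = 150, max_genes = 7000,
                 max_mito = 0.05, min_cells_per_gene = 1)
  expect_true("c3" %in% rownames(q$counts))   # boundary mito fraction kept
  expect_false("c4" %in% rownames(q$counts))  # strictly above removed
  q2 <- qc_filter(counts[1:2, ], meta[1:2, , drop = FALSE], mito,
                  min_genes = 200, max_genes = 7000, max_mito = 0.5,
                  min_cells_per_gene = 1)
  expect_false("c1" %in% rownames(q2$counts))  # 150 < 200 removed
  expect_true("c2" %in% rownames(q2$counts))   # exactly 200 kept
  expect_equal(q2$report$removed_min_genes, 1)
})

test_that("QC filtering is idempotent and matches generator truth", {
  sc <- std_sc()
  qc <- sc$truth$qc
  q1 <- qc_filter(sc$counts, sc$cell_meta, sc$truth$mito_genes,
                  min_genes = qc$min_genes, max_genes = qc$max_genes,
                  max_mito = qc$max_mito, min_cells_per_gene = 3)
  q2 <- qc_filter(q1$counts, q1$cell_meta, q1$mito_genes,
                  min_genes = qc$min_genes, max_genes = qc$max_genes,
                  max_mito = qc$max_mito, min_cells_per_gene = 3)
  expect_equal(dim(q1$counts), dim(q2$counts))
  expect_equal(q2$report$removed_cells, 0)
  # planted violators are exactly the kind each rule removes
  v <- sc$truth$violators
  expect_false(v$low_genes %in% rownames(q1$counts))
  expect_false(v$high_genes %in% rownames(q1$counts))
  expect_false(v$high_mito %in% rownames(q1$counts))
})

test_that("QC profiles carry the published hiPSC and limb thresholds", {
  h <- qc_profiles("hipsc")
  expect_equal(c(h$min_genes, h$max_genes, h$max_mito, h$min_cells_per_gene),
               c(200, 7000, 0.05, 3))
  e <- qc_profiles("embryonic_limb")
  expect_equal(c(e$min_genes, e$max_genes, e$max_mito, e$min_cells_per_gene),
               c(200, 6000, 0.10, 1))
})

test_that("normalization removes depth and zero-total cells", {
  counts <- toy_counts(rbind(c(2, 4, 6), c(1, 2, 3), c(0, 0, 0)))
  expect_warning(nm <- normalize_log(counts), "zero-total")
  expect_equal(nrow(nm), 2)
  # proportional cells become identical after depth scaling
  expect_equal(nm[1, ], nm[2, ])
  # row sums before log equal the median depth
  raw <- expm1(nm)
  expect_equal(unname(rowSums(raw)), rep(median(c(12, 6)), 2))
})

test_that("AUC score reproduces hand-evaluated recovery curves", {
  # 10 genes, T = 5; expression puts the set at chosen ranks
  genes <- paste0("g", sprintf("%02d", 1:10))
  make_cell <- function(rank_of_gene) {
    x <- 10 - rank_of_gene  # higher expression = better rank
    matrix(x, 1, dimnames = list("c1", genes))
  }
  # set genes at ranks 1,2 -> best case, score 1
  cm <- make_cell(setNames(1:10, genes))
  s1 <- aucell_score(cm, c("g01", "g02"), top_frac = 0.5)
  expect_equal(unname(s1$score), 1.0)
  # set genes at ranks 4,5 -> sum = 0+0+0+1+2 = 3, max = 9
  s2 <- aucell_score(cm, c("g04", "g05"), top_frac = 0.5)
  expect_equal(unname(s2$score), 1 / 3)
  # set entirely outside the top T -> 0
  s3 <- aucell_score(cm, c("g09", "g10"), top_frac = 0.5)
  expect_equal(unname(s3$score), 0)
  expect_error(aucell_score(cm, "absent"), "no overlap")
})

test_that("AUC score equals the brute-force oracle on random toys", {
  set.seed(7)
  for (i in 1:30) {
    n_genes <- sample(5:20, 1)
    n_cells <- sample(2:10, 1)
    cm <- matrix(rpois(n_cells * n_genes, 3), n_cells, n_genes,
                 dimnames = list(paste0("c", 1:n_cells),
                                 paste0("g", sprintf("%02d", 1:n_genes))))
    gene_set <- sample(colnames(cm), sample(1:4, 1))
    for (tf in c(0.25, 0.5)) {
      got <- aucell_score(cm, gene_set, top_frac = tf)$score
      want <- vapply(seq_len(n_cells), function(ci) {
        auc_oracle(cm[ci, ], colnames(cm), gene_set, tf)
      }, numeric(1))
      expect_equal(unname(got), want)
    }
  }
})

test_that("scores are invariant to gene-column permutation", {
  sc <- std_sc()
  nm <- normalize_log(sc$counts[1:40, ])
  set.seed(10)
  perm <- sample(ncol(nm))
  s1 <- aucell_score(nm, sc$truth$active_set$genes, top_frac = 0.1)$score
  s2 <- aucell_score(nm[, perm], sc$truth$active_set$genes,
                     top_frac = 0.1)$score
  expect_equal(s1, s2)
  r1 <- rank_sum_score(nm, sc$truth$active_set$genes, max_rank = 100)$score
  r2 <- rank_sum_score(nm[, perm], sc$truth$active_set$genes,
                       max_rank = 100)$score
  expect_equal(r1, r2)
})

test_that("rank-sum score matches hand evaluation and is rank-monotone", {
  genes <- paste0("g", sprintf("%02d", 1:10))
  x <- matrix(10:1, 1, dimnames = list("c1", genes))
  # all m set genes at the top ranks -> U = 0, score 1
  expect_equal(unname(rank_sum_score(x, c("g01", "g02"),
                                     max_rank = 10)$score), 1)
  # all set genes at/beyond max_rank: m=2, max_rank=10, both ranks clip
  # to 10 -> U = 20 - 3 = 17, score = 1 - 17/20 = 0.15
  genes12 <- paste0("g", sprintf("%02d", 1:12))
  x12 <- matrix(12:1, 1, dimnames = list("c1", genes12))
  expect_equal(unname(rank_sum_score(x12, c("g11", "g12"),
                                     max_rank = 10)$score), 0.15)
  # moving a set gene to a better rank never decreases the score
  prev <- -Inf
  for (pos in 9:1) {
    set <- c(genes[pos], "g10")
    s <- unname(rank_sum_score(x, set, max_rank = 10)$score)
    expect_gte(s, prev)
    prev <- s
  }
})

test_that("the planted population ranks first by both scoring methods", {
  sc <- std_sc()
  q <- qc_filter(sc$counts, sc$cell_meta, sc$truth$mito_genes,
                 min_genes = sc$truth$qc$min_genes,
                 max_genes = sc$truth$qc$max_genes,
                 max_mito = sc$truth$qc$max_mito, min_cells_per_gene = 3)
  nm <- normalize_log(q$counts)
  pop <- sc$truth$population_of_cell[rownames(nm)]
  au <- aucell_score(nm, sc$truth$active_set$genes, top_frac = 0.1)$score
  rs <- rank_sum_score(nm, sc$truth$active_set$genes, max_rank = 150)$score
  expect_equal(names(which.max(tapply(au, pop, mean))),
               sc$truth$active_population)
  expect_equal(names(which.max(tapply(rs, pop, mean))),
               sc$truth$active_population)
})

test_that("population proportions sum to one and match a recount", {
  meta <- data.frame(cell = paste0("c", 1:4),
                     time_point = "D1",
                     population = c("A", "A", "B", "C"))
  pp <- population_proportions(meta)
  expect_equal(pp$A, 0.5)
  expect_equal(rowSums(pp[, -1]), 1, ignore_attr = TRUE)

  single <- population_proportions(data.frame(cell = "c", time_point = "D1",
                                              population = "only"))
  expect_equal(single$only, 1)
  expect_error(population_proportions(data.frame()), "empty")

  sc <- std_sc()
  pp2 <- population_proportions(sc$cell_meta)
  tab <- table(sc$cell_meta$time_point, sc$cell_meta$population)
  brute <- sweep(tab, 1, rowSums(tab), "/")
  expect_equal(as.numeric(as.matrix(pp2[, -1])), as.numeric(brute))
})

test_that("ligand-receptor strength is bilinear and finds the planted pair", {
  nm <- toy_counts(matrix(c(2, 0, 4, 1,
                            6, 0, 1, 1), 2, 4, byrow = TRUE))
  meta <- data.frame(cell = rownames(nm), population = c("S", "R"))
  pairs <- data.frame(ligand = c("g01", "g03"), receptor = c("g02", "g04"))
  out <- lr_strength(nm, meta, pairs, senders = "S", receivers = "R")
  # receptor g02 has zero expression in receiver -> strength 0
  expect_equal(out$strength[out$ligand == "g01"], 0)
  expect_equal(out$strength[out$ligand == "g03"], 4 * 1)
  # doubling the ligand mean doubles the strength
  nm2 <- nm; nm2["c01", "g03"] <- 8
  out2 <- lr_strength(nm2, meta, pairs, senders = "S", receivers = "R")
  expect_equal(out2$strength[out2$ligand == "g03"],
               2 * out$strength[out$ligand == "g03"])
  expect_message(lr_strength(nm, meta, data.frame(ligand = "zz",
                                                  receptor = "g02"),
                             "S", "R"),
                 "skipping")
  expect_error(lr_strength(nm, meta, pairs, "S", "ZZ"), "absent")

  sc <- std_sc()
  q <- qc_filter(sc$counts, sc$cell_meta, sc$truth$mito_genes,
                 min_genes = sc$truth$qc$min_genes,
                 max_genes = sc$truth$qc$max_genes,
                 max_mito = sc$truth$qc$max_mito, min_cells_per_gene = 3)
  nm3 <- normalize_log(q$counts)
  decoys <- data.frame(ligand = c(sc$truth$planted_lr[["ligand"]],
                                  "BG0001", "BG0003"),
                       receptor = c(sc$truth$planted_lr[["receptor"]],
                                    "BG0002", "BG0004"))
  ranked <- lr_strength(nm3, q$cell_meta, decoys,
                        senders = sc$truth$senders,
                        receivers = sc$truth$receivers)
  expect_equal(ranked$ligand[1], sc$truth$planted_lr[["ligand"]])
  expect_equal(ranked$receptor[1], sc$truth$planted_lr[["receptor"]])
})

test_that("percent-of-reference handles identity, doubling and zero flags", {
  expr <- rbind(flat = rep(2, 6), up = c(1, 1, 1.5, 1.5, 2, 2),
                zero = rep(0, 6))
  colnames(expr) <- paste0("s", 1:6)
  day <- setNames(rep(c(1, 5, 10), each = 2), colnames(expr))
  res <- percent_of_reference(expr, day, ref_day = 1)
  expect_equal(unname(res$table["flat", ]), c(100, 100, 100))
  expect_equal(unname(res$table["up", "10"]), 200)
  expect_equal(res$flagged, "zero")
  expect_false("zero" %in% rownames(res$table))
  expect_error(percent_of_reference(expr, day, ref_day = 99), "ref_day")
})

test_that("PCA satisfies rank bounds, normalization and trajectory recovery", {
  b <- std_bulk()$human
  two <- b$expr[, 1:2]
  p2 <- pca_scores(two)
  expect_equal(ncol(p2$scores), 1)  # two samples -> one nonzero component

  p <- pca_scores(b$expr)
  expect_equal(sum(p$variance_explained), 1, tolerance = 1e-6)
  # a fixture with a single dominant day-driven factor: PC1 tracks day
  mono <- generate_bulk_multispecies(n_genes = 60, n_modules = 1,
                                     module_size = 40, noise_sd = 0.3,
                                     seed = 5)$human
  pm <- pca_scores(mono$expr)
  expect_gte(abs(cor(pm$scores[, 1], mono$truth$day_of_sample)), 0.9)
  expect_error(pca_scores(b$expr[, 1, drop = FALSE]), "2 samples")
  # deterministic sign: loading of the first gene nonnegative
  first_gene <- sort(rownames(b$expr))[1]
  expect_gte(p$loadings[first_gene, 1], 0)
})
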