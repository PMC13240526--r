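# Signed-hybrid adjacency, TOM, module detection, eigengenes, trait
# correlation and seed-module selection.

test_that("signed-hybrid adjacency follows the power/zero rule", {
  # two genes engineered to known correlations via a third construction
  set.seed(1)
  n <- 50
  x <- rnorm(n)
  make_cor <- function(r) r * x + sqrt(1 - r^2) * rnorm(n)
  # direct algebraic checks on a hand-built correlation structure
  expr <- rbind(g1 = x, g2 = x, g3 = -x + 1e-8 * rnorm(n))
  a <- adjacency_signed_hybrid(expr, beta = 2)
  expect_equal(unname(a["g1", "g2"]), 1.0)           # cor = 1 -> a = 1
  expect_equal(unname(a["g1", "g3"]), 0)             # negative cor -> 0
  expect_equal(unname(diag(a)), rep(1, 3))
  expect_true(isSymmetric(a))

  # cor = 0.5 at beta = 2 gives 0.25: build an exact-correlation pair
  y <- scale(x)[, 1]
  z <- 0.5 * y + sqrt(0.75) * scale(residuals(lm(rnorm(n) ~ y)))[, 1]
  expr2 <- rbind(g1 = y, g2 = z)
  a2 <- adjacency_signed_hybrid(expr2, beta = 2)
  expect_equal(unname(a2["g1", "g2"]), 0.25, tolerance = 1e-10)

  expect_error(adjacency_signed_hybrid(expr[, 1:2], beta = 2),
               "insufficient")
  expect_warning(adjacency_signed_hybrid(rbind(expr, flat = rep(1, n)), 2),
                 "constant")
})

test_that("TOM matches hand evaluation and its limit cases", {
  a <- matrix(c(1, 0.5, 0.2,
                0.5, 1, 0.4,
                0.2, 0.4, 1), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  tom <- tom_similarity(a)
  # TOM_12 = (0.2*0.4 + 0.5) / (min(0.7, 0.9) + 1 - 0.5) = 0.58 / 1.2
  expect_equal(unname(tom["a", "b"]), 0.58 / 1.2, tolerance = 1e-12)
  expect_equal(unname(diag(tom)), rep(1, 3))
  expect_true(isSymmetric(tom))

  id <- diag(4)
  expect_equal(unname(tom_similarity(id)), diag(4))  # no shared neighbors

  # identical binary adjacency rows with a_ij = 1 give perfect overlap
  b <- matrix(c(1, 1, 1,
                1, 1, 1,
                1, 1, 1), 3, 3)
  expect_equal(tom_similarity(b)[1, 2], 1)

  bad <- a; bad[1, 2] <- 0.9
  expect_error(tom_similarity(bad), "symmetric")
})

test_that("adjacency and TOM stay symmetric in [0,1] with unit diagonal", {
  cx <- std_coexpr()
  b <- std_bulk()$human
  adj <- adjacency_signed_hybrid(b$expr, 6)
  tom <- tom_similarity(adj)
  for (m in list(adj, tom)) {
    expect_true(all(m >= 0 & m <= 1 + 1e-12))
    expect_true(isSymmetric(unname(m), tol = 1e-10))
    expect_equal(unname(diag(m)), rep(1, nrow(m)))
  }
})

test_that("module detection recovers planted partitions and names by size", {
  nl <- noiseless_bulk()$human
  cx <- run_coexpr(nl$expr, nl$truth$day_of_sample, nl$truth$seed_genes,
                   beta = 6, min_module_size = 10)
  planted <- nl$truth$module_of_gene
  in_mod <- planted != "none"
  expect_equal(ari_oracle(cx$partition[in_mod], planted[in_mod]), 1)

  # the first color in the sequence goes to a largest detected module
  sizes <- table(cx$partition[cx$partition != "grey"])
  expect_equal(unname(sizes["turquoise"]), max(sizes), ignore_attr = TRUE)

  # all-noise data: the majority of genes stay grey
  noise <- generate_bulk_multispecies(trait_effect = 0, noise_sd = 0.3,
                                      seed = 9)$human
  cxn <- run_coexpr(noise$expr, noise$truth$day_of_sample,
                    noise$truth$seed_genes, beta = 6)
  expect_gt(mean(cxn$partition == "grey"), 0.5)

  # fewer genes than min size: everything grey, with a warning
  small_tom <- tom_similarity(diag(3) * 0 + diag(3))
  dimnames(small_tom) <- list(letters[1:3], letters[1:3])
  expect_warning(p <- detect_modules(small_tom, min_module_size = 10),
                 "grey")
  expect_true(all(p == "grey"))
})

test_that("partition is exhaustive and invariant to sample permutation", {
  b <- std_bulk()$human
  cx <- std_coexpr()
  expect_setequal(names(cx$partition), rownames(b$expr))
  expect_false(any(is.na(cx$partition)))
  perm <- sample(ncol(b$expr))
  cx2 <- run_coexpr(b$expr[, perm], b$truth$day_of_sample[perm],
                    b$truth$seed_genes, beta = 6)
  expect_identical(cx$partition, cx2$partition)
})

test_that("eigengenes satisfy rank-1 cases and the variance contract", {
  b <- std_bulk()$human
  expr <- b$expr
  # single-gene module: eigengene proportional to the z-scored profile
  part <- setNames(rep("grey", nrow(expr)), rownames(expr))
  part[1] <- "solo"
  me <- module_eigengenes(expr, part)
  z <- scale(expr[1, ])[, 1]
  expect_equal(abs(cor(me$eigengenes["solo", ], z)), 1, tolerance = 1e-10)
  expect_equal(sum(me$eigengenes["solo", ]^2), 1)  # unit norm

  # two identical genes: variance explained exactly 1
  dup <- rbind(a = expr[1, ], b = expr[1, ])
  me2 <- module_eigengenes(dup, c(a = "m", b = "m"))
  expect_equal(unname(me2$variance_explained["m"]), 1)

  # noiseless planted module is essentially rank 1
  nl <- noiseless_bulk()$human
  truth_part <- ifelse(nl$truth$module_of_gene == "M1", "m1", "grey")
  names(truth_part) <- names(nl$truth$module_of_gene)
  me3 <- module_eigengenes(nl$expr, truth_part)
  expect_gte(unname(me3$variance_explained["m1"]), 0.99)
})

test_that("eigengene sign convention is independent of gene-row order", {
  b <- std_bulk()$human
  cx <- std_coexpr()
  perm <- sample(nrow(b$expr))
  me1 <- module_eigengenes(b$expr, cx$partition)
  me2 <- module_eigengenes(b$expr[perm, ], cx$partition)
  common <- intersect(rownames(me1$eigengenes), rownames(me2$eigengenes))
  expect_equal(me1$eigengenes[common, ], me2$eigengenes[common, ],
               tolerance = 1e-8)
})

test_that("trait correlation matches a permutation oracle", {
  me <- std_coexpr()$eigengenes
  day <- std_bulk()$human$truth$day_of_sample
  tc <- module_trait_correlation(me, day)
  expect_true(all(abs(tc$cor) <= 1))

  # analytic p from t on n-2 df vs brute-force permutation p
  set.seed(5)
  n <- 12
  d <- rep(c(1, 4, 7, 10), each = 3)
  e <- scale(d + rnorm(n, sd = 6))[, 1]   # moderately correlated eigengene
  tc1 <- module_trait_correlation(matrix(e, 1, dimnames = list("m", NULL)), d)
  r_obs <- abs(cor(e, d))
  perm_r <- replicate(1e5, abs(cor(e, sample(d))))
  p_perm <- (sum(perm_r >= r_obs) + 1) / (1e5 + 1)
  expect_equal(tc1$p, p_perm, tolerance = 0.1)  # Monte-Carlo slack

  # monotone limit and orthogonal case
  inc <- matrix(scale(d)[, 1], 1, dimnames = list("up", NULL))
  expect_equal(module_trait_correlation(inc, d)$cor, 1, tolerance = 1e-10)
  orth <- matrix(rep(c(1, 0, -1), 4), 1, dimnames = list("o", NULL))
  expect_equal(module_trait_correlation(orth, d)$cor, 0, tolerance = 1e-10)

  expect_error(module_trait_correlation(me, rep(3, ncol(me))), "constant")
})

test_that("soft-power selection honors target, invalid input and fallback", {
  b <- std_bulk()$human
  expect_error(pick_soft_power(b$expr, r2_target = 1.1), "r2_target")
  res <- pick_soft_power(b$expr, candidate_powers = 1:20, r2_target = 0.8)
  expect_true(res$power %in% 1:20 || res$fallback_used)
  if (!res$fallback_used) {
    # returned power is the smallest qualifying candidate
    qual <- res$fit_table$power[res$fit_table$r2 >= 0.8]
    expect_equal(res$power, min(qual))
  }
  imp <- pick_soft_power(b$expr, candidate_powers = 1:3, r2_target = 0.9999)
  expect_true(imp$fallback_used)
  expect_equal(imp$power, 9)
})

test_that("seed modules are the trait-significant modules holding seeds", {
  cx <- std_coexpr()
  b <- std_bulk()$human
  sel <- seed_modules(cx$partition, b$truth$seed_genes, cx$trait_cor)
  seed_labels <- unique(cx$partition[b$truth$seed_genes])
  sig <- cx$trait_cor$module[cx$trait_cor$p < 0.05]
  expect_setequal(sel$modules, intersect(setdiff(seed_labels, "grey"), sig))

  expect_error(seed_modules(cx$partition, c("NOPE1"), cx$trait_cor),
               "NOPE1")
  # seed forced into grey is reported, not selected
  part <- cx$partition
  part[b$truth$seed_genes[1]] <- "grey"
  sel2 <- seed_modules(part, b$truth$seed_genes[1], cx$trait_cor)
  expect_equal(sel2$unassigned_seeds, b$truth$seed_genes[1])
  expect_length(sel2$modules, 0)
})
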