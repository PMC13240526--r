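# STRING edge loading, module subgraphs, first-neighbor extraction,
# network merging and hub ranking.

write_string_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write_tsv(df, path)
  path
}

test_that("STRING loader handles scale dialects, threshold and dedup", {
  path <- write_string_tsv(data.frame(
    protein1 = c("A", "B", "C", "C", "D"),
    protein2 = c("B", "C", "A", "A", "D"),
    combined_score = c(400, 390, 500, 700, 900)))
  g <- load_string_edges(path, threshold = 0.4)
  el <- igraph::as_data_frame(g, what = "edges")
  # 400 on the 0-1000 dialect is exactly 0.4 and kept (inclusive rule)
  expect_true(any(el$from == "A" & el$to == "B"))
  # 0.39 falls below threshold
  expect_false(any((el$from == "B" & el$to == "C") |
                     (el$from == "C" & el$to == "B")))
  # duplicate A-C pair deduplicated keeping max score
  ac <- el[(el$from == "A" & el$to == "C") | (el$from == "C" & el$to == "A"), ]
  expect_equal(nrow(ac), 1)
  expect_equal(ac$score, 0.7)
  # self-loop dropped
  expect_false(igraph::any_loop(g))

  # already-normalized dialect passes through unchanged
  p2 <- write_string_tsv(data.frame(protein1 = "A", protein2 = "B",
                                    combined_score = 0.55))
  g2 <- load_string_edges(p2, threshold = 0.4)
  expect_equal(igraph::E(g2)$score, 0.55)

  expect_error(load_string_edges(p2, threshold = 1.5), "threshold")
  p3 <- write_string_tsv(data.frame(x = 1, y = 2))
  expect_error(load_string_edges(p3), "format")
})

test_that("id_map remaps proteins and drops unmapped rows", {
  path <- write_string_tsv(data.frame(
    protein1 = c("p1", "p2"), protein2 = c("p2", "p9"),
    combined_score = c(800, 800)))
  idm <- data.frame(protein = c("p1", "p2"), gene = c("G1", "G2"))
  expect_message(g <- load_string_edges(path, id_map = idm), "unmapped")
  expect_setequal(igraph::V(g)$name, c("G1", "G2"))
})

test_that("module subgraph induces edges and keeps isolated module genes", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("A", "B", "C"), to = c("B", "C", "A"),
               score = 0.5), directed = FALSE)
  sub <- module_subgraph(g, c("A", "B"))
  expect_equal(igraph::ecount(sub), 1)
  sub2 <- module_subgraph(g, c("A", "B", "ZZ"))
  expect_true("ZZ" %in% igraph::V(sub2)$name)
  expect_equal(igraph::degree(sub2)[["ZZ"]], 0)
  expect_warning(module_subgraph(g, "QQ"), "empty")
})

test_that("first neighbors equals the depth-1 rule on canonical shapes", {
  path3 <- igraph::graph_from_data_frame(
    data.frame(from = c("A", "B"), to = c("B", "C")), directed = FALSE)
  net <- first_neighbors(path3, "A")
  expect_setequal(igraph::V(net$graph)$name, c("A", "B"))
  expect_equal(igraph::ecount(net$graph), 1)

  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("S", paste0("L", 1:5))
  snet <- first_neighbors(star, "S")
  expect_equal(igraph::vcount(snet$graph), 6)
  expect_equal(unname(snet$degree["S"]), 5)

  expect_error(first_neighbors(path3, "ZZ"), "no seed")
  expect_warning(net2 <- first_neighbors(path3, c("A", "ZZ")), "isolated")
  expect_true("ZZ" %in% names(net2$seed_flags))
  expect_true(net2$seed_flags[["ZZ"]])
})

test_that("first neighbors matches the BFS oracle on random graphs", {
  set.seed(99)
  for (i in 1:100) {
    g <- random_graph(sample(5:50, 1))
    seeds <- sample(igraph::V(g)$name, sample(1:3, 1))
    net <- suppressWarnings(first_neighbors(g, seeds))
    expect_equal(sort(igraph::V(net$graph)$name), bfs1_oracle(g, seeds))
    # every non-seed node is adjacent to at least one seed
    for (v in igraph::V(net$graph)$name) {
      if (!net$seed_flags[[v]] && igraph::vcount(net$graph) > 1) {
        nb <- igraph::neighbors(g, v)$name
        expect_true(any(nb %in% seeds))
      }
    }
  }
})

test_that("merge is idempotent, commutative and provenance-unioning", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("A", "B"), to = c("B", "C"), score = 0.5),
    directed = FALSE)
  n1 <- first_neighbors(g, "A", provenance = "turquoise")
  n2 <- first_neighbors(g, "C", provenance = "blue")

  same <- merge_networks(list(n1, n1))
  expect_setequal(igraph::V(same$graph)$name, igraph::V(n1$graph)$name)
  expect_equal(igraph::ecount(same$graph), igraph::ecount(n1$graph))

  m12 <- merge_networks(list(n1, n2))
  m21 <- merge_networks(list(n2, n1))
  expect_setequal(igraph::V(m12$graph)$name, igraph::V(m21$graph)$name)
  expect_equal(igraph::ecount(m12$graph), igraph::ecount(m21$graph))
  # B entered from both modules
  expect_setequal(m12$provenance[["B"]], c("turquoise", "blue"))
  # degrees recomputed on the merged graph
  expect_equal(unname(m12$degree["B"]), 2)

  # disjoint networks: node counts add
  h <- igraph::graph_from_data_frame(
    data.frame(from = "X", to = "Y", score = 1), directed = FALSE)
  nd <- first_neighbors(h, "X")
  md <- merge_networks(list(n1, nd))
  expect_equal(igraph::vcount(md$graph),
               igraph::vcount(n1$graph) + igraph::vcount(nd$graph))

  empty <- merge_networks(list())
  expect_equal(igraph::vcount(empty$graph), 0)
})

test_that("hub ranking sorts by degree with alphabetical ties", {
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("S", paste0("L", 1:5))
  net <- first_neighbors(star, "S")
  hb <- hub_ranking(net)
  expect_equal(hb$gene[1], "S")
  expect_equal(hb$degree[1], 5)
  # leaves all tie at degree 1: alphabetical
  expect_equal(hb$gene[-1], sort(paste0("L", 1:5)))
  expect_equal(nrow(hub_ranking(net, top_n = 3)), 3)

  # ranking equals brute-force adjacency counts on a random fixture
  set.seed(4)
  g <- random_graph(30, p = 0.2)
  rnet <- suppressWarnings(first_neighbors(g, c("N01", "N02")))
  hb2 <- hub_ranking(rnet, top_n = 100)
  adj <- igraph::as_adjacency_matrix(rnet$graph, sparse = FALSE)
  brute <- rowSums(adj)
  expect_equal(setNames(hb2$degree, hb2$gene),
               brute[order(-brute, names(brute))])
})

test_that("raising the STRING threshold never adds seed-network nodes", {
  b <- std_bulk()$human
  cx <- std_coexpr()
  path <- tempfile(fileext = ".tsv")
  ppi <- generate_ppi(b$truth, seed = 6)
  el <- igraph::as_data_frame(ppi, what = "edges")
  write_tsv(data.frame(protein1 = el$from, protein2 = el$to,
                       combined_score = round(el$score * 1000)), path)
  prev <- NULL
  for (thr in c(0.4, 0.6, 0.8)) {
    g <- load_string_edges(path, threshold = thr)
    net <- suppressWarnings(
      build_seed_network(g, cx$partition, b$truth$seed_genes))
    nodes <- igraph::V(net$graph)$name
    if (!is.null(prev)) expect_true(all(nodes %in% prev))
    prev <- nodes
  }
})

test_that("seed network export writes edge TSV and GraphML", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("A", "B"), to = c("B", "C"), score = 0.5),
    directed = FALSE)
  net <- first_neighbors(g, "A", provenance = "turquoise")
  prefix <- file.path(withr::local_tempdir(), "net")
  paths <- write_seed_network(net, prefix)
  expect_true(all(file.exists(paths)))
  reread <- igraph::read_graph(paths[2], format = "graphml")
  expect_setequal(igraph::V(reread)$name, igraph::V(net$graph)$name)
  expect_true("is_seed" %in% igraph::vertex_attr_names(reread))
})
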