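test_that("network construction applies the inclusive confidence threshold", {
  edges <- tibble::tibble(
    gene_a = c("A", "B"), gene_b = c("B", "C"), confidence = c(0.95, 0.50)
  )
  net <- build_network(c("A", "B", "C"), edges, min_confidence = 0.90)
  expect_equal(igraph::vcount(net), 3)
  expect_equal(igraph::ecount(net), 1)
  expect_setequal(isolated_nodes(net)$symbol, "C")

  boundary <- tibble::tibble(gene_a = "A", gene_b = "B", confidence = 0.900)
  expect_equal(igraph::ecount(build_network(c("A", "B"), boundary, 0.900)), 1)
  expect_error(build_network(character(0), edges), "empty")
})

test_that("interaction ingest drops self-pairs, collapses duplicates, handles STRING 0-999 scores", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "protein1\tprotein2\tcombined_score",
    "A\tA\t999",
    "A\tB\t910",
    "B\tA\t400",
    "b\tC\t200"
  ), tmp)
  tab <- read_interactions(tmp)
  expect_equal(nrow(tab), 2) # self-pair dropped, A-B collapsed
  ab <- tab[tab$gene_a == "A" & tab$gene_b == "B", ]
  expect_equal(ab$confidence, 0.910) # max of duplicates, scores / 1000
  expect_error(
    interaction_table(tibble::tibble(gene_a = "A", gene_b = "B", confidence = 1.2)),
    "\\[0, 1\\]"
  )
})

test_that("raising the confidence threshold never adds edges (monotonicity)", {
  set.seed(31)
  genes <- sprintf("G%d", 1:12)
  edges <- tibble::tibble(
    gene_a = sample(genes, 40, replace = TRUE),
    gene_b = sample(genes, 40, replace = TRUE),
    confidence = runif(40)
  )
  edges <- edges[edges$gene_a != edges$gene_b, ]
  thresholds <- c(0.2, 0.5, 0.8, 0.95)
  counts <- vapply(
    thresholds,
    function(th) igraph::ecount(build_network(genes, edges, th)),
    numeric(1)
  )
  expect_true(all(diff(counts) <= 0))
})

test_that("centrality matches hand-enumerated closed forms", {
  # path A-B-C
  path <- build_network(
    c("A", "B", "C"),
    tibble::tibble(gene_a = c("A", "B"), gene_b = c("B", "C"), confidence = 1)
  )
  rep_path <- centrality(path)
  got <- rep_path[order(rep_path$gene), ]
  expect_equal(got$degree, c(1L, 2L, 1L))
  expect_equal(got$betweenness, c(0, 1, 0))
  expect_equal(attr(rep_path, "mean_degree"), 4 / 3)
  expect_equal(attr(rep_path, "mean_betweenness"), 1 / 3)
  expect_equal(select_key_nodes(rep_path)$symbol, "B")

  # star: center X, three leaves
  star <- build_network(
    c("X", "L1", "L2", "L3"),
    tibble::tibble(gene_a = "X", gene_b = c("L1", "L2", "L3"), confidence = 1)
  )
  rep_star <- centrality(star)
  expect_equal(rep_star$betweenness[rep_star$gene == "X"], 3)
  expect_equal(sum(rep_star$betweenness), 3)
  expect_equal(attr(rep_star, "mean_degree"), 1.5)
  expect_equal(attr(rep_star, "mean_betweenness"), 0.75)
  expect_equal(select_key_nodes(rep_star)$symbol, "X")

  # complete graph: all betweenness zero, every node is key by symmetry
  k4_edges <- t(combn(c("A", "B", "C", "D"), 2))
  k4 <- build_network(
    c("A", "B", "C", "D"),
    tibble::tibble(gene_a = k4_edges[, 1], gene_b = k4_edges[, 2], confidence = 1)
  )
  rep_k4 <- centrality(k4)
  expect_equal(rep_k4$betweenness, rep(0, 4))
  expect_setequal(select_key_nodes(rep_k4)$symbol, c("A", "B", "C", "D"))
  expect_equal(isolated_nodes(k4)$symbol, character(0))
})

test_that("betweenness agrees with the all-simple-paths oracle on random graphs", {
  for (seed in 1:60) {
    g <- random_test_graph(seed)
    rep <- centrality(g$graph)
    oracle <- oracle_betweenness(g$adj)
    expect_equal(
      rep$betweenness[match(rownames(g$adj), rep$gene)],
      oracle,
      tolerance = 1e-9
    )
    # degree sum identity
    expect_equal(sum(rep$degree), 2 * igraph::ecount(g$graph))
  }
})

test_that("pair double-counting flag doubles every betweenness value", {
  g <- random_test_graph(123)
  single <- centrality(g$graph)
  double <- centrality(g$graph, double_count_pairs = TRUE)
  expect_equal(double$betweenness, 2 * single$betweenness)
})

test_that("node removal yields the induced subgraph", {
  g <- build_network(
    c("A", "B", "C", "D"),
    tibble::tibble(
      gene_a = c("A", "B", "C"), gene_b = c("B", "C", "D"), confidence = 1
    )
  )
  expect_equal(igraph::vcount(remove_nodes(g, character(0))), 4) # identity
  expect_equal(igraph::vcount(remove_nodes(g, c("A", "B", "C", "D"))), 0)
  sub <- remove_nodes(g, "B")
  expect_setequal(igraph::V(sub)$name, c("A", "C", "D"))
  expect_equal(igraph::ecount(sub), 1) # only C-D survives
})

test_that("key-node rule uses inclusive comparisons against both means", {
  # at least one node always clears the degree mean (max >= mean)
  for (seed in 1:20) {
    g <- random_test_graph(seed)
    rep <- centrality(g$graph)
    expect_true(any(rep$degree >= attr(rep, "mean_degree")))
  }
})

test_that("planted network structure is recovered from a generated bundle", {
  tmp <- withr::local_tempdir()
  b <- simulate_bundle(generator_config(seed = 17), dir = tmp)
  net <- build_network(
    gene_set(b$manifest$stage2_genes),
    read_interactions(b$paths$interactions),
    min_confidence = 0.900
  )
  iso <- isolated_nodes(net)
  expect_equal(iso$symbol, b$manifest$isolate_gene)
  rep <- centrality(remove_nodes(net, iso))
  expect_setequal(select_key_nodes(rep)$symbol, b$manifest$hub_genes)
})
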