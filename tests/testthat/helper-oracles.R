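# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: the hypergeometric oracle enumerates
# every possible draw, and the betweenness oracle enumerates every simple
# path between every node pair.

# P(X >= k) by exhaustive enumeration of all C(N, n) draws from a labelled
# population. Feasible for N <= 12.
oracle_hyper_tail <- function(k, K, n, N) {
  if (n == 0) return(if (k == 0) 1 else 0)
  pop <- c(rep(1, K), rep(0, N - K))
  draws <- utils::combn(N, n)
  hits <- colSums(matrix(pop[draws], nrow = n))
  mean(hits >= k)
}

# Freeman betweenness by enumerating all simple paths per unordered pair,
# keeping the shortest, and attributing fractional counts to interior nodes.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  if (n < 3) return(btw)
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      paths <- list()
      dfs <- function(node, visited, path) {
        if (node == t) {
          paths[[length(paths) + 1]] <<- path
          return(invisible(NULL))
        }
        for (nb in which(adj[node, ] > 0)) {
          if (!(nb %in% visited)) dfs(nb, c(visited, nb), c(path, nb))
        }
      }
      dfs(s, s, s)
      if (length(paths) == 0) next
      lens <- lengths(paths)
      shortest <- paths[lens == min(lens)]
      sigma <- length(shortest)
      for (p in shortest) {
        interior <- p[-c(1, length(p))]
        btw[interior] <- btw[interior] + 1 / sigma
      }
    }
  }
  btw
}

# Seeded Erdos-Renyi-style random graph as an igraph plus adjacency matrix.
random_test_graph <- function(seed) {
  set.seed(seed)
  n <- sample(3:7, 1)
  adj <- matrix(0L, n, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < 0.4) adj[i, j] <- adj[j, i] <- 1L
    }
  }
  rownames(adj) <- colnames(adj) <- sprintf("N%d", 1:n)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  list(graph = g, adj = adj)
}

# Small literature corpus shared by corpus tests.
toy_corpus <- function() {
  literature_corpus(
    documents = data.frame(
      doc_id = c("d1", "d2"),
      text = c("brown fat thermogenesis", "white fat")
    ),
    links = data.frame(
      gene_id = c("g1", "g2", "g3"),
      symbol = c("UCP1", "PPARG", "LEP"),
      doc_id = c("d1", "d1", "d2")
    )
  )
}

# Two-term enrichment-result stub with overlapping member lists.
enrich_result_stub <- function() {
  tibble::tibble(genes = list(c("A", "B"), c("B", "C")))
}

# Minimal all-detail drug catalog builder for funnel tests.
toy_catalog <- function(rows) {
  drug_catalog(tibble::tibble(
    name = rows$name,
    targets = rows$targets,
    global_status = rows$status,
    mechanism_class = rows$class,
    has_trial_detail = rows$detail
  ))
}
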