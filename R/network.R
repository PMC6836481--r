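#' Read a STRING-dialect interaction table
#'
#' Tab-separated with header columns `protein1`, `protein2`,
#' `combined_score`. Scores may be the STRING 0-999 integer dialect (divided
#' by 1000 on ingest) or already 0-1 decimals; the two dialects are
#' distinguished by any score exceeding 1. Self-pairs are dropped and
#' unordered duplicate pairs collapsed keeping the maximum confidence.
#'
#' @param path Path to the edge-list TSV.
#' @return A tibble with columns `gene_a`, `gene_b`, `confidence`.
#' @export
read_interactions <- function(path) {
  raw <- read_tsv_strict(path, c("protein1", "protein2", "combined_score"))
  score <- suppressWarnings(as.numeric(raw$combined_score))
  if (any(is.na(score))) {
    bad <- which(is.na(score))[1]
    stop(sprintf("%s: line %d: combined_score is not numeric", path, bad + 1L),
      call. = FALSE
    )
  }
  if (any(score > 1)) score <- score / 1000
  interaction_table(tibble::tibble(
    gene_a = raw$protein1, gene_b = raw$protein2, confidence = score
  ))
}

#' Normalize an interaction edge list
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`, `confidence`
#'   (confidence already on the 0-1 scale).
#' @return A tibble with self-pairs removed and unordered duplicates
#'   collapsed to their maximum confidence; endpoints uppercased.
#' @export
interaction_table <- function(edges) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("gene_a", "gene_b", "confidence") %in% names(edges)))
  if (any(edges$confidence < 0 | edges$confidence > 1)) {
    stop("interaction_table: confidence must lie in [0, 1]", call. = FALSE)
  }
  edges$gene_a <- normalize_symbol(edges$gene_a)
  edges$gene_b <- normalize_symbol(edges$gene_b)
  edges <- dplyr::filter(edges, .data$gene_a != .data$gene_b)
  # canonical unordered orientation, then keep the best-scoring duplicate
  flip <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[flip]
  edges$gene_a[flip] <- edges$gene_b[flip]
  edges$gene_b[flip] <- tmp
  edges |>
    dplyr::group_by(.data$gene_a, .data$gene_b) |>
    dplyr::summarise(confidence = max(.data$confidence), .groups = "drop") |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
}

#' Build the high-confidence interaction network
#'
#' Nodes are the candidate genes; edges are the interactions whose two
#' endpoints both belong to the candidate set and whose confidence is at or
#' above the threshold (inclusive, matching a STRING "highest confidence"
#' screen at 0.900). Genes with no qualifying interaction stay in the
#' network as isolates.
#'
#' @param genes A `gene_set` (or character vector of symbols).
#' @param interactions A tibble as returned by [interaction_table()] /
#'   [read_interactions()].
#' @param min_confidence Inclusive confidence threshold in \[0, 1\].
#' @return An undirected simple `igraph` graph.
#' @export
build_network <- function(genes, interactions, min_confidence = 0.900) {
  if (is.character(genes)) genes <- gene_set(genes)
  if (nrow(genes) == 0) stop("build_network: empty gene set", call. = FALSE)
  stopifnot(
    is.numeric(min_confidence), length(min_confidence) == 1,
    min_confidence >= 0, min_confidence <= 1
  )
  interactions <- interaction_table(interactions)
  syms <- unique(genes$symbol)
  keep <- dplyr::filter(
    interactions,
    .data$confidence >= min_confidence,
    .data$gene_a %in% syms,
    .data$gene_b %in% syms
  )
  igraph::graph_from_data_frame(
    keep[, c("gene_a", "gene_b")],
    directed = FALSE,
    vertices = data.frame(name = syms)
  )
}

#' Isolated nodes of a network
#'
#' @param net An `igraph` graph.
#' @return A `gene_set` of the zero-degree nodes.
#' @export
isolated_nodes <- function(net) {
  stopifnot(inherits(net, "igraph"))
  deg <- igraph::degree(net)
  gene_set(names(deg)[deg == 0], label = "isolates")
}

#' Induced subgraph after dropping nodes
#'
#' @param net An `igraph` graph.
#' @param drop A `gene_set` or character vector of node names to remove.
#' @return The induced subgraph on the remaining nodes.
#' @export
remove_nodes <- function(net, drop) {
  stopifnot(inherits(net, "igraph"))
  drop_syms <- if (is.data.frame(drop)) drop$symbol else normalize_symbol(drop)
  keep <- setdiff(igraph::V(net)$name, drop_syms)
  igraph::induced_subgraph(net, vids = keep)
}

#' Degree and betweenness centrality report
#'
#' Degree is the incident-edge count. Betweenness is the Freeman measure:
#' for node v, the sum over unordered node pairs (s, t), s != t != v, of the
#' fraction of shortest s-t paths passing through v — undirected,
#' unnormalized, endpoints excluded, each unordered pair counted once;
#' disconnected pairs contribute nothing. The arithmetic means over the
#' network's nodes are attached as attributes: the key-node rule compares
#' each node against them.
#'
#' @param net A nonempty `igraph` graph.
#' @param double_count_pairs If `TRUE`, counts each pair in both directions
#'   (doubling every betweenness value); provided for sensitivity checks
#'   against tools that use the directed-sum convention.
#' @return A `centrality_report`: a tibble with columns `gene`, `degree`,
#'   `betweenness`, ordered by decreasing degree (ties by gene), with
#'   attributes `mean_degree` and `mean_betweenness`.
#' @export
centrality <- function(net, double_count_pairs = FALSE) {
  stopifnot(inherits(net, "igraph"))
  if (igraph::vcount(net) == 0) {
    stop("centrality: network has no nodes", call. = FALSE)
  }
  nm <- igraph::V(net)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(net)))
  deg <- igraph::degree(net)
  btw <- igraph::betweenness(net, directed = FALSE, normalized = FALSE)
  if (double_count_pairs) btw <- 2 * btw
  out <- tibble::tibble(
    gene = nm,
    degree = as.integer(deg),
    betweenness = as.numeric(btw)
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$degree), .data$gene)
  structure(out,
    mean_degree = mean(out$degree),
    mean_betweenness = mean(out$betweenness),
    class = c("centrality_report", class(tibble::tibble()))
  )
}

#' Key-node selection by the dual mean-threshold rule
#'
#' A key node has degree and betweenness both greater than or equal to the
#' corresponding network-wide arithmetic mean. Comparisons round both sides
#' to 10 decimal places first, so a value equal to its mean up to floating
#' noise is never excluded by a spurious strict inequality.
#'
#' @param report A `centrality_report`.
#' @return A `gene_set` of the key nodes.
#' @export
select_key_nodes <- function(report) {
  stopifnot(inherits(report, "centrality_report"))
  if (nrow(report) == 0) stop("select_key_nodes: empty report", call. = FALSE)
  md <- round(attr(report, "mean_degree"), 10)
  mb <- round(attr(report, "mean_betweenness"), 10)
  keep <- round(report$degree, 10) >= md & round(report$betweenness, 10) >= mb
  gene_set(report$gene[keep], label = "key nodes")
}

#' Write a centrality report as TSV
#'
#' @param report A `centrality_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_centrality_tsv <- function(report, path) {
  key <- select_key_nodes(report)
  flat <- tibble::as_tibble(report)
  flat$is_key <- flat$gene %in% key$symbol
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
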