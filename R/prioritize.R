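#' Augment key nodes with an anchor gene set
#'
#' The screening cascade keeps the network's key nodes and merges in the
#' member genes of a designated "anchor" annotation term (by default the
#' most-enriched biological process, brown fat cell differentiation), on the
#' rationale that every member of that process is a plausible browning
#' target even if it is not a network hub. The result is the deduplicated
#' union: key genes first, in their incoming order, then the novel anchor
#' genes alphabetically. A `source` column records where each gene came
#' from (`"key_node"`, `"anchor"`, or `"both"`).
#'
#' @param key_genes A `gene_set` (or character vector) of key network nodes.
#' @param anchor A `gene_set` (or character vector) of anchor-term members.
#' @return A `gene_set` with an extra `source` column.
#' @export
#' @examples
#' augment_with_anchor(c("PPARG", "LEP"), c("PPARG", "UCP1", "PRDM16"))
augment_with_anchor <- function(key_genes, anchor) {
  if (is.character(key_genes)) key_genes <- gene_set(key_genes, label = "key nodes")
  if (is.character(anchor)) anchor <- gene_set(anchor, label = "anchor")
  if (nrow(key_genes) == 0 || nrow(anchor) == 0) {
    stop("augment_with_anchor: both gene sets must be nonempty", call. = FALSE)
  }
  key <- tibble::as_tibble(key_genes)
  anc <- tibble::as_tibble(anchor)
  key$source <- ifelse(key$gene_id %in% anc$gene_id, "both", "key_node")
  novel <- dplyr::filter(anc, !(.data$gene_id %in% key$gene_id))
  novel <- dplyr::arrange(novel, .data$symbol, .data$gene_id)
  novel$source <- "anchor"
  out <- dplyr::bind_rows(key, novel)
  res <- gene_set(out, label = "final target genes")
  # gene_set() re-sorts alphabetically; restore key-first ordering
  res <- res[match(out$gene_id, res$gene_id), , drop = FALSE]
  structure(res,
    label = "final target genes",
    class = c("gene_set", class(tibble::tibble()))
  )
}

#' Write the final gene list as TSV
#'
#' @param final_genes Output of [augment_with_anchor()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list_tsv <- function(final_genes, path) {
  flat <- tibble::as_tibble(final_genes)
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
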