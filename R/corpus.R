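#' Literature corpus: documents and gene-document links
#'
#' Emulates a literature-association service (a pubmed2ensembl-style lookup)
#' over local files: a documents table mapping document ids to keyword text,
#' and a links table associating genes with documents. Queries extract the
#' genes linked to at least one document whose keyword text contains the
#' query phrase as a case-insensitive exact substring.
#'
#' @param documents Data frame with columns `doc_id`, `text`.
#' @param links Data frame with columns `gene_id`, `symbol`, `doc_id`.
#' @return A `literature_corpus` object (a list of the two validated tibbles).
#' @export
literature_corpus <- function(documents, links) {
  documents <- tibble::as_tibble(documents)
  links <- tibble::as_tibble(links)
  stopifnot(
    all(c("doc_id", "text") %in% names(documents)),
    all(c("gene_id", "symbol", "doc_id") %in% names(links))
  )
  documents$doc_id <- as.character(documents$doc_id)
  links$doc_id <- as.character(links$doc_id)
  links$gene_id <- as.character(links$gene_id)
  links$symbol <- normalize_symbol(links$symbol)
  if (anyDuplicated(documents$doc_id) > 0) {
    stop("literature_corpus: duplicate document ids", call. = FALSE)
  }
  bad <- setdiff(links$doc_id, documents$doc_id)
  if (length(bad) > 0) {
    stop(
      "literature_corpus: links reference unknown documents: ",
      paste(utils::head(bad, 5), collapse = ", "),
      call. = FALSE
    )
  }
  links <- dplyr::distinct(links)
  structure(
    list(documents = documents, links = links),
    class = "literature_corpus"
  )
}

#' @export
print.literature_corpus <- function(x, ...) {
  cat(sprintf(
    "<literature_corpus> %d documents, %d gene-document links, %d genes\n",
    nrow(x$documents), nrow(x$links), dplyr::n_distinct(x$links$gene_id)
  ))
  invisible(x)
}

#' Read a literature corpus from TSV files
#'
#' The documents file has header columns `doc_id`, `text`; the links file has
#' `gene_id`, `symbol`, `doc_id`. Both are UTF-8 tab-separated with a header
#' row.
#'
#' @param documents_path,links_path Paths to the two TSV files.
#' @return A `literature_corpus`.
#' @export
read_corpus <- function(documents_path, links_path) {
  documents <- read_tsv_strict(documents_path, c("doc_id", "text"))
  links <- read_tsv_strict(links_path, c("gene_id", "symbol", "doc_id"))
  literature_corpus(documents, links)
}

#' Genes linked to documents matching a query phrase
#'
#' Matching is case-insensitive exact substring over the document keyword
#' text: no stemming or tokenization, so the rule is fully auditable.
#'
#' @param corpus A `literature_corpus`.
#' @param term Nonempty query phrase.
#' @return A `gene_set` labelled with the query term.
#' @export
#' @examples
#' corp <- literature_corpus(
#'   documents = data.frame(doc_id = c("d1", "d2"),
#'                          text = c("brown fat thermogenesis", "white fat")),
#'   links = data.frame(gene_id = c("g1", "g2", "g3"),
#'                      symbol = c("UCP1", "PPARG", "LEP"),
#'                      doc_id = c("d1", "d1", "d2"))
#' )
#' query_genes(corp, "brown fat")
query_genes <- function(corpus, term) {
  stopifnot(inherits(corpus, "literature_corpus"))
  if (!is.character(term) || length(term) != 1 || !nzchar(stringr::str_trim(term))) {
    stop("query_genes: query term must be a nonempty string", call. = FALSE)
  }
  hit_docs <- corpus$documents$doc_id[
    stringr::str_detect(
      stringr::str_to_lower(corpus$documents$text),
      stringr::fixed(stringr::str_to_lower(term))
    )
  ]
  hits <- dplyr::filter(corpus$links, .data$doc_id %in% hit_docs)
  gene_set(
    dplyr::distinct(hits, .data$gene_id, .data$symbol),
    label = term
  )
}

#' Intersect query gene lists
#'
#' Returns the genes present (by `gene_id`) in every input set — the
#' starting point of the screening cascade.
#'
#' @param sets A non-empty list of `gene_set` objects.
#' @return A `gene_set`; its label concatenates the input labels.
#' @export
intersect_queries <- function(sets) {
  if (!is.list(sets) || length(sets) == 0 || inherits(sets, "data.frame")) {
    stop("intersect_queries: need a non-empty list of gene sets", call. = FALSE)
  }
  common <- Reduce(intersect, lapply(sets, function(s) s$gene_id))
  first <- sets[[1]]
  gene_set(
    dplyr::filter(tibble::as_tibble(first), .data$gene_id %in% common),
    label = paste(vapply(sets, set_label, character(1)), collapse = " & ")
  )
}

# Strict TSV reader shared by ingest functions: checks the header and reports
# the file and missing columns on contract violation.
read_tsv_strict <- function(path, required_cols) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  out <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing <- setdiff(required_cols, names(out))
  if (length(missing) > 0) {
    stop(sprintf(
      "%s: missing required column(s): %s",
      path, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  out
}
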