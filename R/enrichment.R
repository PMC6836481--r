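#' Hypergeometric upper-tail probability
#'
#' Probability of observing at least `k` annotated genes when drawing `n`
#' genes without replacement from a universe of `N` genes of which `K` carry
#' the annotation:
#' \deqn{P(X \ge k) = \sum_{i=k}^{\min(K,n)} \frac{{K \choose i}{N-K \choose n-i}}{{N \choose n}}}
#' Terms are evaluated in log space (`lchoose`) and combined with a
#' log-sum-exp so the result stays finite and accurate for p-values far
#' below the double underflow threshold used naively (enrichment p-values of
#' 1e-300 and smaller are routine for large overlaps).
#'
#' @param k Observed overlap count, `0 <= k <= min(K, n)`.
#' @param K Number of annotated genes in the universe.
#' @param n Query size.
#' @param N Universe size.
#' @return `P(X >= k)` as a double in (0, 1].
#' @export
#' @examples
#' hypergeom_tail(4, K = 5, n = 4, N = 10) # 5/210
hypergeom_tail <- function(k, K, n, N) {
  check_count <- function(x, nm) {
    if (length(x) != 1 || is.na(x) || x < 0 || x != floor(x)) {
      stop(sprintf("hypergeom_tail: %s must be a single nonnegative integer", nm),
        call. = FALSE
      )
    }
  }
  check_count(k, "k"); check_count(K, "K"); check_count(n, "n"); check_count(N, "N")
  if (K > N || n > N || k > min(K, n)) {
    stop(sprintf(
      "hypergeom_tail: invalid counts (k=%d, K=%d, n=%d, N=%d): need K<=N, n<=N, k<=min(K,n)",
      k, K, n, N
    ), call. = FALSE)
  }
  if (k == 0) return(1)
  i <- seq.int(max(k, n - (N - K)), min(K, n))
  logp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(logp)
  min(1, exp(m + log(sum(exp(logp - m)))))
}

#' Multiple-testing correction
#'
#' Corrects a vector of raw p-values, preserving input order. `"BH"` is the
#' Benjamini-Hochberg step-up with cumulative-minimum enforcement capped at
#' 1; `"bonferroni"` multiplies by the number of tests (capped at 1);
#' `"none"` returns the input.
#'
#' @param pvals Numeric vector of raw p-values in (0, 1].
#' @param method One of `"BH"`, `"bonferroni"`, `"none"`.
#' @return Corrected p-values in the input's order.
#' @export
correct_pvalues <- function(pvals, method = c("BH", "bonferroni", "none")) {
  method <- match.arg(method)
  if (length(pvals) == 0) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop("correct_pvalues: p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = method)
}

#' Construct an annotation database
#'
#' @param terms A named list of character vectors (term name -> member gene
#'   symbols), or a tibble with columns `term`, `genes` (list column).
#' @param namespace `"BP"` (biological process) or `"PATHWAY"`.
#' @param universe_size Size `N` of the annotation universe. Defaults to the
#'   number of distinct genes across all terms; real annotation universes are
#'   larger than that union, so supply the known value when available.
#' @return An `annotation_db` object.
#' @export
annotation_db <- function(terms, namespace = c("BP", "PATHWAY"),
                          universe_size = NULL) {
  namespace <- match.arg(namespace)
  if (is.data.frame(terms)) {
    stopifnot(all(c("term", "genes") %in% names(terms)))
    terms <- stats::setNames(terms$genes, terms$term)
  }
  stopifnot(is.list(terms), !is.null(names(terms)), all(nzchar(names(terms))))
  terms <- lapply(terms, function(g) sort(unique(normalize_symbol(g))))
  if (any(lengths(terms) == 0)) {
    stop("annotation_db: every term must have at least one gene", call. = FALSE)
  }
  if (anyDuplicated(names(terms)) > 0) {
    stop("annotation_db: duplicate term names", call. = FALSE)
  }
  union_size <- length(unique(unlist(terms, use.names = FALSE)))
  if (is.null(universe_size)) universe_size <- union_size
  if (universe_size < union_size) {
    stop("annotation_db: universe_size smaller than the union of term gene sets",
      call. = FALSE
    )
  }
  structure(
    list(namespace = namespace, terms = terms, universe_size = universe_size),
    class = "annotation_db"
  )
}

#' @export
print.annotation_db <- function(x, ...) {
  cat(sprintf(
    "<annotation_db> namespace=%s, %d terms, universe N=%d\n",
    x$namespace, length(x$terms), x$universe_size
  ))
  invisible(x)
}

#' Read an annotation database from a GMT file
#'
#' GMT: one gene set per line — term name, description, then member gene
#' symbols, tab-separated.
#'
#' @param path Path to the GMT file.
#' @inheritParams annotation_db
#' @return An `annotation_db`.
#' @export
read_gmt <- function(path, namespace = c("BP", "PATHWAY"), universe_size = NULL) {
  if (!file.exists(path)) stop(sprintf("GMT file not found: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(stringr::str_trim(lines))]
  fields <- stringr::str_split(lines, "\t")
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    stop(sprintf(
      "%s: line %d: GMT lines need term, description and at least one gene",
      path, short[1]
    ), call. = FALSE)
  }
  terms <- stats::setNames(
    lapply(fields, function(f) f[-(1:2)]),
    vapply(fields, `[[`, character(1), 1)
  )
  annotation_db(terms, namespace = namespace, universe_size = universe_size)
}

#' Gene-set enrichment against an annotation database
#'
#' For every term sharing at least one gene with the query, computes the
#' overlap `k`, the term size `K`, the hypergeometric upper-tail p-value at
#' the database's universe size `N`, and the corrected p-value across those
#' terms. Terms with zero overlap carry no evidence and are excluded before
#' correction. Returns the terms whose corrected p-value is at or below the
#' cutoff, sorted by corrected p-value with ties broken by term name.
#'
#' @param query A `gene_set` (or character vector of symbols).
#' @param db An `annotation_db`.
#' @param cutoff Significance cutoff on the corrected p-value, in (0, 1).
#' @param method Correction method passed to [correct_pvalues()].
#' @return An `enrichment_result` tibble with columns `term`, `k`, `K`, `n`,
#'   `N`, `p_raw`, `p_corrected` and a list column `genes` holding the
#'   overlap symbols (sorted).
#' @export
enrich <- function(query, db, cutoff, method = c("BH", "bonferroni", "none")) {
  method <- match.arg(method)
  stopifnot(inherits(db, "annotation_db"))
  if (is.character(query)) query <- gene_set(query)
  if (nrow(query) == 0) stop("enrich: query gene set is empty", call. = FALSE)
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0 || cutoff >= 1) {
    stop("enrich: cutoff must lie in (0, 1)", call. = FALSE)
  }
  qsym <- unique(query$symbol)
  n <- length(qsym)
  N <- db$universe_size
  if (n > N) {
    stop("enrich: query larger than the annotation universe", call. = FALSE)
  }
  rows <- purrr::map(names(db$terms), function(tn) {
    members <- db$terms[[tn]]
    overlap <- sort(intersect(qsym, members))
    if (length(overlap) == 0) return(NULL)
    tibble::tibble(
      term = tn,
      k = length(overlap),
      K = length(members),
      n = n,
      N = N,
      p_raw = hypergeom_tail(length(overlap), length(members), n, N),
      genes = list(overlap)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      term = character(), k = integer(), K = integer(), n = integer(),
      N = integer(), p_raw = double(), p_corrected = double(), genes = list()
    )
  } else {
    out$p_corrected <- correct_pvalues(out$p_raw, method)
    out <- dplyr::filter(out, .data$p_corrected <= cutoff)
    out <- dplyr::arrange(out, .data$p_corrected, .data$term)
    out <- dplyr::relocate(out, "genes", .after = "p_corrected")
  }
  structure(out, class = c("enrichment_result", class(tibble::tibble())))
}

#' Union of member genes across enrichment results
#'
#' Deduplicated union of the overlap genes of all selected terms — the gene
#' list each enrichment stage hands to the next stage.
#'
#' @param results An `enrichment_result` tibble (or any tibble with a
#'   `genes` list column of symbol vectors).
#' @return A `gene_set`.
#' @export
genes_of <- function(results) {
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0) return(gene_set(character(0), label = "enriched genes"))
  gene_set(
    unique(unlist(results$genes, use.names = FALSE)),
    label = "enriched genes"
  )
}

#' Write an enrichment result as TSV
#'
#' Columns mirror a published enrichment summary table: term, overlap count,
#' term size, raw and corrected p-values, member genes semicolon-joined.
#'
#' @param results An `enrichment_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(results, path) {
  flat <- tibble::as_tibble(results)
  flat$genes <- vapply(flat$genes, paste, character(1), collapse = ";")
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
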