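#' Construct a gene set
#'
#' A gene set is the pipeline's currency: a tibble with columns `gene_id` and
#' `symbol`, deduplicated by `gene_id` and ordered deterministically
#' (alphabetically by symbol, ties broken by `gene_id`). Symbols are
#' normalized to trimmed uppercase on construction, so membership tests are
#' case-insensitive. A `label` attribute records provenance.
#'
#' @param x A data frame with columns `gene_id` and `symbol`, or a character
#'   vector of symbols (in which case `gene_id` is taken equal to the symbol).
#' @param label Provenance string attached to the set.
#' @return A tibble of class `gene_set` with columns `gene_id`, `symbol`.
#' @export
#' @examples
#' gene_set(c("Ucp1", "PPARG", "ucp1"), label = "demo")
gene_set <- function(x, label = "") {
  if (is.character(x)) {
    sym <- normalize_symbol(x)
    x <- tibble::tibble(gene_id = sym, symbol = sym)
  }
  stopifnot(is.data.frame(x), all(c("gene_id", "symbol") %in% names(x)))
  out <- tibble::as_tibble(x)
  out$symbol <- normalize_symbol(out$symbol)
  out$gene_id <- as.character(out$gene_id)
  if (any(!nzchar(out$symbol))) {
    stop("gene_set: empty symbols are not allowed", call. = FALSE)
  }
  out <- dplyr::distinct(out, .data$gene_id, .keep_all = TRUE)
  out <- dplyr::arrange(out, .data$symbol, .data$gene_id)
  structure(out,
    label = label,
    class = c("gene_set", class(tibble::tibble()))
  )
}

normalize_symbol <- function(x) toupper(stringr::str_trim(as.character(x)))

#' @export
print.gene_set <- function(x, ...) {
  lbl <- attr(x, "label")
  cat(sprintf(
    "<gene_set> %d gene%s%s\n", nrow(x), if (nrow(x) == 1) "" else "s",
    if (nzchar(lbl)) paste0("  [", lbl, "]") else ""
  ))
  NextMethod()
}

#' Label of a gene set
#' @param x A `gene_set`.
#' @return The provenance label string.
#' @export
set_label <- function(x) attr(x, "label") %||% ""
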