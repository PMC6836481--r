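#' Default development-status whitelist
#'
#' The relatively mature development stages retained by the screening
#' funnel: launched, the three clinical-trial phases, pre-registration, and
#' registered.
#' @return Character vector of status tokens.
#' @export
default_status_whitelist <- function() {
  c(
    "launched",
    "phase i clinical trial", "phase ii clinical trial",
    "phase iii clinical trial",
    "pre-registration", "registered"
  )
}

#' Default mechanism-of-action blacklist
#'
#' Mechanism classes excluded on efficacy/safety grounds: beta-1
#' adrenoceptor agonists and antagonists (cardiovascular off-target risk),
#' interleukin-6 antagonists, and CREB-binding protein inhibitors.
#' @return Character vector of mechanism-class tokens.
#' @export
default_mechanism_blacklist <- function() {
  c(
    "beta-1 adrenoceptor antagonist", "beta-1 adrenoceptor agonist",
    "interleukin-6 antagonist", "creb-binding protein inhibitor"
  )
}

# status tokens a catalog may carry; the whitelist is a subset
drug_status_vocabulary <- function() {
  c(
    default_status_whitelist(),
    "preclinical", "discontinued", "suspended", "no development reported"
  )
}

normalize_token <- function(x) stringr::str_to_lower(stringr::str_trim(x))

#' Construct a drug catalog
#'
#' @param drugs Data frame with columns `name`, `targets` (semicolon-joined
#'   gene symbols or a list column of symbol vectors), `global_status`,
#'   `mechanism_class`, `has_trial_detail` (logical or "true"/"false").
#' @return A `drug_catalog` tibble with `targets` as a list column of
#'   uppercase symbols; status and mechanism tokens trimmed and lowercased.
#' @export
drug_catalog <- function(drugs) {
  drugs <- tibble::as_tibble(drugs)
  req <- c("name", "targets", "global_status", "mechanism_class", "has_trial_detail")
  missing <- setdiff(req, names(drugs))
  if (length(missing) > 0) {
    stop("drug_catalog: missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(drugs$name) > 0) {
    stop("drug_catalog: duplicate drug names", call. = FALSE)
  }
  if (!is.list(drugs$targets)) {
    drugs$targets <- stringr::str_split(drugs$targets, ";")
  }
  drugs$targets <- lapply(drugs$targets, function(t) {
    t <- normalize_symbol(t)
    t[nzchar(t)]
  })
  if (any(lengths(drugs$targets) == 0)) {
    stop("drug_catalog: every drug needs at least one target", call. = FALSE)
  }
  drugs$global_status <- normalize_token(drugs$global_status)
  bad <- setdiff(unique(drugs$global_status), drug_status_vocabulary())
  if (length(bad) > 0) {
    stop("drug_catalog: unknown status token(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  drugs$mechanism_class <- normalize_token(drugs$mechanism_class)
  if (is.character(drugs$has_trial_detail)) {
    drugs$has_trial_detail <- normalize_token(drugs$has_trial_detail) == "true"
  }
  stopifnot(is.logical(drugs$has_trial_detail), !any(is.na(drugs$has_trial_detail)))
  structure(drugs, class = c("drug_catalog", class(tibble::tibble())))
}

#' Read a drug catalog from TSV
#'
#' Header columns: `name`, `targets` (semicolon-joined symbols),
#' `global_status`, `mechanism_class`, `has_trial_detail` (true/false).
#'
#' @param path Path to the catalog TSV.
#' @return A `drug_catalog` tibble.
#' @export
read_drug_catalog <- function(path) {
  drug_catalog(read_tsv_strict(
    path,
    c("name", "targets", "global_status", "mechanism_class", "has_trial_detail")
  ))
}

#' Drugs hitting at least one target gene
#'
#' @param catalog A `drug_catalog`.
#' @param genes A `gene_set` or character vector of target symbols.
#' @return The matching rows, catalog order preserved.
#' @export
match_drugs <- function(catalog, genes) {
  syms <- if (is.data.frame(genes)) genes$symbol else normalize_symbol(genes)
  keep <- vapply(catalog$targets, function(t) any(t %in% syms), logical(1))
  catalog[keep, , drop = FALSE]
}

#' Filter drugs by development status
#'
#' @param drugs A `drug_catalog` (or filtered subset).
#' @param allowed Status whitelist; defaults to [default_status_whitelist()].
#' @return Rows whose `global_status` is in `allowed`, order preserved.
#' @export
filter_status <- function(drugs, allowed = default_status_whitelist()) {
  if (length(allowed) == 0) {
    stop("filter_status: allowed status list must be nonempty", call. = FALSE)
  }
  drugs[drugs$global_status %in% normalize_token(allowed), , drop = FALSE]
}

#' Keep drugs with documented development detail
#'
#' Models the manual screen that discards drugs whose development process is
#' not documented in trial records: the catalog carries the outcome as an
#' explicit boolean column.
#'
#' @param drugs A `drug_catalog` (or filtered subset).
#' @return Rows with `has_trial_detail` true, order preserved.
#' @export
filter_detail <- function(drugs) {
  drugs[drugs$has_trial_detail, , drop = FALSE]
}

#' Drop blacklisted mechanism-of-action classes
#'
#' @param drugs A `drug_catalog` (or filtered subset).
#' @param blacklist Mechanism classes to remove; defaults to
#'   [default_mechanism_blacklist()]. An empty blacklist is the identity.
#' @return Rows whose `mechanism_class` is not blacklisted, order preserved.
#' @export
filter_mechanism <- function(drugs, blacklist = default_mechanism_blacklist()) {
  if (length(blacklist) == 0) return(drugs)
  drugs[!(drugs$mechanism_class %in% normalize_token(blacklist)), , drop = FALSE]
}

#' Tabulate surviving drugs by mechanism class
#'
#' @param drugs A `drug_catalog` (or filtered subset).
#' @return A tibble with columns `mechanism_class`, `n_drugs`, sorted by
#'   decreasing count then class name; counts sum to `nrow(drugs)`.
#' @export
tabulate_classes <- function(drugs) {
  if (nrow(drugs) == 0) {
    return(tibble::tibble(mechanism_class = character(), n_drugs = integer()))
  }
  drugs |>
    tibble::as_tibble() |>
    dplyr::count(.data$mechanism_class, name = "n_drugs") |>
    dplyr::arrange(dplyr::desc(.data$n_drugs), .data$mechanism_class)
}

#' Run the drug screening funnel
#'
#' Applies the full cascade — target matching, status whitelist,
#' development-detail filter, mechanism blacklist — and reports stage
#' survivor counts plus the final class tally.
#'
#' @param catalog A `drug_catalog`.
#' @param genes Target `gene_set` (or character vector of symbols).
#' @param allowed Status whitelist.
#' @param blacklist Mechanism blacklist.
#' @return A `funnel_report`: list with `stages` (tibble: `stage`, `n`),
#'   `class_tally` (tibble), and `drugs` (the surviving catalog rows).
#' @export
drug_funnel <- function(catalog, genes,
                        allowed = default_status_whitelist(),
                        blacklist = default_mechanism_blacklist()) {
  matched <- match_drugs(catalog, genes)
  by_status <- filter_status(matched, allowed)
  by_detail <- filter_detail(by_status)
  final <- filter_mechanism(by_detail, blacklist)
  structure(
    list(
      stages = tibble::tibble(
        stage = c("matched", "status", "detail", "mechanism"),
        n = c(nrow(matched), nrow(by_status), nrow(by_detail), nrow(final))
      ),
      class_tally = tabulate_classes(final),
      drugs = final
    ),
    class = "funnel_report"
  )
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("<funnel_report>\n")
  for (i in seq_len(nrow(x$stages))) {
    cat(sprintf("  %-10s %d\n", x$stages$stage[i], x$stages$n[i]))
  }
  if (nrow(x$class_tally) > 0) {
    cat("  final classes:\n")
    for (i in seq_len(nrow(x$class_tally))) {
      cat(sprintf(
        "    %-40s %d\n",
        x$class_tally$mechanism_class[i], x$class_tally$n_drugs[i]
      ))
    }
  }
  invisible(x)
}

#' Write a funnel report as JSON
#'
#' @param report A `funnel_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_funnel_json <- function(report, path) {
  jsonlite::write_json(
    list(
      stages = report$stages,
      class_tally = report$class_tally,
      drugs = report$drugs$name
    ),
    path,
    dataframe = "rows", auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}
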