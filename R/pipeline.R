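#' Pipeline configuration
#'
#' Collects every tunable of the screening cascade with the published
#' defaults: the three literature query phrases, the biological-process
#' cutoff 1.00e-07, the pathway cutoff 1.00e-06, BH correction, the 0.900
#' interaction-confidence threshold, the anchor term "brown fat cell
#' differentiation", the development-status whitelist and the
#' mechanism-of-action blacklist.
#'
#' @param documents,links,bp_gmt,pathway_gmt,interactions,drugs Input file
#'   paths (corpus TSVs, two GMT files, STRING-dialect edge list, drug
#'   catalog TSV). A bundle from [simulate_bundle()] supplies all six.
#' @param query_terms Character vector of literature query phrases.
#' @param bp_cutoff,pathway_cutoff Corrected-p-value cutoffs for the two
#'   enrichment stages.
#' @param correction Multiple-testing correction method.
#' @param min_confidence Inclusive interaction-confidence threshold.
#' @param anchor_term Stage-1 term whose member genes augment the key nodes.
#' @param status_whitelist,mechanism_blacklist Drug-funnel token lists.
#' @param universe_size Annotation universe size N; `NULL` uses each GMT
#'   file's own gene union.
#' @param out_dir Output directory for stage artifacts, or `NULL` to skip
#'   writing.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(
    documents, links, bp_gmt, pathway_gmt, interactions, drugs,
    query_terms = c("brown-fat-like development", "brown fat", "brown adipose tissue"),
    bp_cutoff = 1.00e-07,
    pathway_cutoff = 1.00e-06,
    correction = c("BH", "bonferroni", "none"),
    min_confidence = 0.900,
    anchor_term = "brown fat cell differentiation",
    status_whitelist = default_status_whitelist(),
    mechanism_blacklist = default_mechanism_blacklist(),
    universe_size = NULL,
    out_dir = NULL) {
  correction <- match.arg(correction)
  stopifnot(
    bp_cutoff > 0, bp_cutoff < 1, pathway_cutoff > 0, pathway_cutoff < 1,
    min_confidence >= 0, min_confidence <= 1,
    length(query_terms) >= 1
  )
  structure(
    list(
      documents = documents, links = links, bp_gmt = bp_gmt,
      pathway_gmt = pathway_gmt, interactions = interactions, drugs = drugs,
      query_terms = query_terms, bp_cutoff = bp_cutoff,
      pathway_cutoff = pathway_cutoff, correction = correction,
      min_confidence = min_confidence, anchor_term = anchor_term,
      status_whitelist = status_whitelist,
      mechanism_blacklist = mechanism_blacklist,
      universe_size = universe_size, out_dir = out_dir
    ),
    class = "pipeline_config"
  )
}

#' Run the full screening cascade
#'
#' Executes literature query extraction and intersection, two-stage
#' enrichment, network construction with isolate removal and key-node
#' selection, anchor augmentation, and the drug funnel. Empty intermediate
#' gene sets raise a warning (not an error) and propagate: downstream
#' stages receive empty input and emit empty output, which is the honest
#' outcome of an over-strict screen. When `config$out_dir` is set, every
#' intermediate gene list, the centrality report, the final gene and drug
#' lists, and the funnel JSON are written there; identical inputs and
#' config yield byte-identical files.
#'
#' @param config A [pipeline_config()].
#' @return A `browning_pipeline` list: `query_sets`, `candidates`,
#'   `stage1`, `stage1_genes`, `stage2`, `stage2_genes`, `network`,
#'   `isolates`, `centrality`, `key_genes`, `anchor_genes`, `final_genes`,
#'   `funnel`, and `provenance` (parameter snapshot plus per-stage counts).
#' @export
run_browning_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  corpus <- read_corpus(config$documents, config$links)
  bp_db <- read_gmt(config$bp_gmt, "BP", universe_size = config$universe_size)
  pathway_db <- read_gmt(config$pathway_gmt, "PATHWAY",
    universe_size = config$universe_size
  )
  interactions <- read_interactions(config$interactions)
  catalog <- read_drug_catalog(config$drugs)

  empty_gs <- function(label) gene_set(character(0), label = label)
  warn_empty <- function(x, stage) {
    if (nrow(x) == 0) warning(sprintf("pipeline stage '%s' is empty", stage), call. = FALSE)
    x
  }

  query_sets <- lapply(config$query_terms, function(t) query_genes(corpus, t))
  candidates <- warn_empty(intersect_queries(query_sets), "query intersection")

  stage1 <- if (nrow(candidates) > 0) {
    enrich(candidates, bp_db, config$bp_cutoff, config$correction)
  } else {
    enrich_empty()
  }
  stage1_genes <- warn_empty(genes_of(stage1), "stage-1 enriched genes")

  stage2 <- if (nrow(stage1_genes) > 0) {
    enrich(stage1_genes, pathway_db, config$pathway_cutoff, config$correction)
  } else {
    enrich_empty()
  }
  stage2_genes <- warn_empty(genes_of(stage2), "stage-2 enriched genes")

  if (nrow(stage2_genes) > 0) {
    net <- build_network(stage2_genes, interactions, config$min_confidence)
    isolates <- isolated_nodes(net)
    pruned <- remove_nodes(net, isolates)
    report <- if (igraph::vcount(pruned) > 0) centrality(pruned) else NULL
    key_genes <- if (!is.null(report)) select_key_nodes(report) else empty_gs("key nodes")
  } else {
    net <- NULL
    isolates <- empty_gs("isolates")
    report <- NULL
    key_genes <- empty_gs("key nodes")
  }
  if (nrow(key_genes) == 0) warning("pipeline stage 'key nodes' is empty", call. = FALSE)

  anchor_genes <- if (config$anchor_term %in% stage1$term) {
    gene_set(
      stage1$genes[[match(config$anchor_term, stage1$term)]],
      label = config$anchor_term
    )
  } else {
    if (nrow(stage1) > 0) {
      warning(sprintf(
        "anchor term '%s' not among stage-1 enriched terms", config$anchor_term
      ), call. = FALSE)
    }
    empty_gs(config$anchor_term)
  }
  final_genes <- if (nrow(key_genes) > 0 && nrow(anchor_genes) > 0) {
    augment_with_anchor(key_genes, anchor_genes)
  } else if (nrow(key_genes) > 0) {
    key_genes
  } else {
    anchor_genes
  }

  funnel <- drug_funnel(
    catalog, final_genes,
    allowed = config$status_whitelist,
    blacklist = config$mechanism_blacklist
  )

  result <- structure(
    list(
      query_sets = query_sets, candidates = candidates,
      stage1 = stage1, stage1_genes = stage1_genes,
      stage2 = stage2, stage2_genes = stage2_genes,
      network = net, isolates = isolates, centrality = report,
      key_genes = key_genes, anchor_genes = anchor_genes,
      final_genes = final_genes, funnel = funnel,
      provenance = list(
        parameters = config[setdiff(names(config), "out_dir")],
        stage_counts = c(
          candidates = nrow(candidates),
          stage1_terms = nrow(stage1), stage1_genes = nrow(stage1_genes),
          stage2_terms = nrow(stage2), stage2_genes = nrow(stage2_genes),
          isolates = nrow(isolates), key_genes = nrow(key_genes),
          final_genes = nrow(final_genes),
          drugs_final = nrow(funnel$drugs)
        )
      )
    ),
    class = "browning_pipeline"
  )
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

enrich_empty <- function() {
  structure(
    tibble::tibble(
      term = character(), k = integer(), K = integer(), n = integer(),
      N = integer(), p_raw = double(), p_corrected = double(), genes = list()
    ),
    class = c("enrichment_result", class(tibble::tibble()))
  )
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_gene_list_tsv(result$candidates, p("candidate_genes.tsv"))
  write_enrichment_tsv(result$stage1, p("stage1_bp_enrichment.tsv"))
  write_gene_list_tsv(result$stage1_genes, p("stage1_genes.tsv"))
  write_enrichment_tsv(result$stage2, p("stage2_pathway_enrichment.tsv"))
  write_gene_list_tsv(result$stage2_genes, p("stage2_genes.tsv"))
  if (!is.null(result$centrality)) {
    write_centrality_tsv(result$centrality, p("centrality_report.tsv"))
  }
  write_gene_list_tsv(result$key_genes, p("key_genes.tsv"))
  write_gene_list_tsv(result$final_genes, p("final_genes.tsv"))
  readr::write_tsv(
    dplyr::mutate(
      tibble::as_tibble(result$funnel$drugs),
      targets = vapply(.data$targets, paste, character(1), collapse = ";")
    ),
    p("final_drugs.tsv"),
    progress = FALSE
  )
  write_funnel_json(result$funnel, p("funnel.json"))
  invisible(out_dir)
}

#' @export
print.browning_pipeline <- function(x, ...) {
  cat("<browning_pipeline>\n  stage survivors:\n")
  counts <- x$provenance$stage_counts
  for (nm in names(counts)) cat(sprintf("    %-14s %d\n", nm, counts[[nm]]))
  invisible(x)
}
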