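#' Configuration for the synthetic-data generator
#'
#' Defines the planted structure of a synthetic pipeline input bundle: a
#' literature corpus whose three query lists share a common core, two
#' annotation namespaces with planted enriched terms among decoys, a
#' hub-dominated interaction network with one isolate, and a drug catalog
#' stratified by development status, detail flag, and mechanism class.
#' Defaults emulate the published study's shape at desk scale: three query
#' terms, a query core in the tens of genes, enrichment overlaps like the
#' published tables (anchor term overlapping 13 core genes), three network
#' hubs, and an eligible drug cohort with the published class composition
#' (18 PPAR-gamma agonists, 4 beta-3 adrenoceptor agonists, 1 insulin
#' sensitizer, 3 insulins, 6 lipase clearing factor stimulants, 1 other).
#'
#' @param seed Integer seed; everything the generator emits is a
#'   deterministic function of the config including the seed.
#' @param genome_size Number of genes in the synthetic genome (annotation
#'   universe size N).
#' @param core_size Number of genes common to all three query lists.
#' @param exclusive_per_query Genes unique to each query list.
#' @param query_terms The three query phrases planted in document text.
#' @param bp_planted Tibble with columns `term`, `K`, `k`: planted
#'   biological-process terms (term size and overlap with the query core).
#'   The first row is the anchor term.
#' @param pathway_planted Tibble with columns `term`, `K`, `k`: planted
#'   pathway terms (overlap drawn from the stage-1 gene union).
#' @param decoy_terms Decoy term count per namespace.
#' @param decoy_size_range Size range for decoy terms.
#' @param hub_count Planted hub nodes among the stage-2 genes.
#' @param decoy_edge_count Sub-threshold decoy interactions.
#' @param planted_confidence,decoy_confidence Confidence ranges for planted
#'   (at or above the screening threshold) and decoy (strictly below) edges.
#' @param eligible_classes Named integer vector: mechanism class ->
#'   number of fully eligible drugs surviving the whole funnel.
#' @param n_off_target,n_bad_status,n_no_detail,n_blacklisted Planted
#'   ineligible drugs removed at (respectively) the matching, status,
#'   detail, and mechanism stages.
#' @return A `generator_config` list.
#' @export
generator_config <- function(
    seed = 1L,
    genome_size = 2000L,
    core_size = 25L,
    exclusive_per_query = 35L,
    query_terms = c("brown-fat-like development", "brown fat", "brown adipose tissue"),
    bp_planted = tibble::tibble(
      term = c(
        "brown fat cell differentiation",
        "response to cold",
        "lipid metabolic process"
      ),
      K = c(26L, 29L, 40L),
      k = c(13L, 10L, 12L)
    ),
    pathway_planted = tibble::tibble(
      term = c("ppar signaling pathway", "adipocytokine signaling pathway"),
      K = c(25L, 25L),
      k = c(15L, 12L)
    ),
    decoy_terms = 20L,
    decoy_size_range = c(10L, 50L),
    hub_count = 3L,
    decoy_edge_count = 60L,
    planted_confidence = c(0.90, 0.99),
    decoy_confidence = c(0.15, 0.85),
    eligible_classes = c(
      "ppar-gamma agonist" = 18L,
      "beta-3 adrenoceptor agonist" = 4L,
      "insulin sensitizer" = 1L,
      "insulin" = 3L,
      "lipase clearing factor stimulant" = 6L,
      "other" = 1L
    ),
    n_off_target = 30L,
    n_bad_status = 20L,
    n_no_detail = 10L,
    n_blacklisted = 6L) {
  cfg <- list(
    seed = as.integer(seed),
    genome_size = as.integer(genome_size),
    core_size = as.integer(core_size),
    exclusive_per_query = as.integer(exclusive_per_query),
    query_terms = query_terms,
    bp_planted = tibble::as_tibble(bp_planted),
    pathway_planted = tibble::as_tibble(pathway_planted),
    decoy_terms = as.integer(decoy_terms),
    decoy_size_range = as.integer(decoy_size_range),
    hub_count = as.integer(hub_count),
    decoy_edge_count = as.integer(decoy_edge_count),
    planted_confidence = planted_confidence,
    decoy_confidence = decoy_confidence,
    eligible_classes = eligible_classes,
    n_off_target = as.integer(n_off_target),
    n_bad_status = as.integer(n_bad_status),
    n_no_detail = as.integer(n_no_detail),
    n_blacklisted = as.integer(n_blacklisted)
  )
  stopifnot(
    length(cfg$query_terms) == 3,
    all(c("term", "K", "k") %in% names(cfg$bp_planted)),
    all(c("term", "K", "k") %in% names(cfg$pathway_planted))
  )
  if (any(cfg$bp_planted$k > cfg$bp_planted$K) ||
    any(cfg$pathway_planted$k > cfg$pathway_planted$K)) {
    stop("generator_config: planted overlap k cannot exceed term size K",
      call. = FALSE
    )
  }
  if (any(cfg$bp_planted$k > cfg$core_size)) {
    stop("generator_config: planted BP overlap exceeds the query core size",
      call. = FALSE
    )
  }
  if (cfg$decoy_confidence[2] >= cfg$planted_confidence[1]) {
    stop("generator_config: decoy confidence range must lie strictly below the planted range",
      call. = FALSE
    )
  }
  structure(cfg, class = "generator_config")
}

#' Generate a synthetic pipeline bundle with planted ground truth
#'
#' Writes all four pipeline inputs (literature corpus as documents + links
#' TSVs, two GMT annotation files, a STRING-dialect edge list, a drug
#' catalog TSV) plus a JSON truth manifest into `dir`. Generation is
#' self-validating: the planted enrichment signal, network topology, and
#' drug funnel are re-run through the package's own analysis functions, and
#' generation fails loudly if the planted truth would not be recovered
#' (for example a decoy term slipping under the cutoff, or a planted hub
#' not clearing both centrality means).
#'
#' Output is deterministic: the same config (including seed) yields a
#' byte-identical bundle.
#'
#' @param config A [generator_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths) and `manifest`
#'   (the planted truth as an R list; also written to `manifest.json`).
#' @export
simulate_bundle <- function(config = generator_config(), dir) {
  stopifnot(inherits(config, "generator_config"))
  if (missing(dir)) stop("simulate_bundle: output directory required", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old_seed)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(config$seed,
    kind = "Mersenne-Twister", normal.kind = "Inversion",
    sample.kind = "Rejection"
  )

  genome <- sprintf("SYNG%04d", seq_len(config$genome_size))

  ## ---- corpus: three query lists sharing a planted core -----------------
  core <- sort(sample(genome, config$core_size))
  pool <- setdiff(genome, core)
  exclusive <- list()
  for (i in 1:3) {
    exclusive[[i]] <- sort(sample(pool, config$exclusive_per_query))
    pool <- setdiff(pool, exclusive[[i]])
  }
  query_lists <- lapply(1:3, function(i) sort(c(core, exclusive[[i]])))

  docs <- list()
  links <- list()
  for (i in 1:3) {
    doc_ids <- sprintf("doc_q%d_%02d", i, 1:5)
    docs[[i]] <- tibble::tibble(
      doc_id = doc_ids,
      text = sprintf("study %02d of %s in adipocytes", 1:5, config$query_terms[i])
    )
    links[[i]] <- tibble::tibble(
      gene_id = query_lists[[i]],
      symbol = query_lists[[i]],
      doc_id = sample(doc_ids, length(query_lists[[i]]), replace = TRUE)
    )
  }
  # background genes linked to neutral documents (no query term in text)
  bg_genes <- sort(sample(pool, 100))
  bg_doc_ids <- sprintf("doc_bg_%02d", 1:10)
  docs[[4]] <- tibble::tibble(
    doc_id = bg_doc_ids,
    text = sprintf("background study %02d of metabolic signaling", 1:10)
  )
  links[[4]] <- tibble::tibble(
    gene_id = bg_genes, symbol = bg_genes,
    doc_id = sample(bg_doc_ids, length(bg_genes), replace = TRUE)
  )
  documents <- dplyr::bind_rows(docs)
  link_tbl <- dplyr::arrange(dplyr::bind_rows(links), .data$gene_id, .data$doc_id)

  ## ---- annotation namespaces: planted terms among decoys ----------------
  make_terms <- function(planted, overlap_pool, avoid) {
    terms <- list()
    overlaps <- list()
    for (i in seq_len(nrow(planted))) {
      ov <- sort(sample(overlap_pool, planted$k[i]))
      filler <- sort(sample(
        setdiff(genome, union(avoid, ov)),
        planted$K[i] - planted$k[i]
      ))
      terms[[planted$term[i]]] <- sort(c(ov, filler))
      overlaps[[planted$term[i]]] <- ov
    }
    list(terms = terms, overlaps = overlaps)
  }
  decoy_sets <- function(prefix) {
    sizes <- sample(
      seq(config$decoy_size_range[1], config$decoy_size_range[2]),
      config$decoy_terms,
      replace = TRUE
    )
    stats::setNames(
      lapply(sizes, function(s) sort(sample(genome, s))),
      sprintf("%s_decoy_%02d", prefix, seq_len(config$decoy_terms))
    )
  }

  bp <- make_terms(config$bp_planted, core, core)
  bp_terms <- c(bp$terms, decoy_sets("bp"))
  bp_db <- annotation_db(bp_terms, "BP", universe_size = config$genome_size)

  stage1_query <- gene_set(core, label = "query core")
  stage1 <- enrich(stage1_query, bp_db, cutoff = 1e-7, method = "BH")
  if (!setequal(stage1$term, config$bp_planted$term)) {
    stop(
      "simulate_bundle: stage-1 enrichment does not recover exactly the ",
      "planted BP terms (a decoy passed or a planted term failed the cutoff); ",
      "adjust the planted (k, K) design",
      call. = FALSE
    )
  }
  stage1_genes <- genes_of(stage1)

  path <- make_terms(config$pathway_planted, stage1_genes$symbol, stage1_genes$symbol)
  pathway_terms <- c(path$terms, decoy_sets("pathway"))
  pathway_db <- annotation_db(pathway_terms, "PATHWAY",
    universe_size = config$genome_size
  )
  stage2 <- enrich(stage1_genes, pathway_db, cutoff = 1e-6, method = "BH")
  if (!setequal(stage2$term, config$pathway_planted$term)) {
    stop(
      "simulate_bundle: stage-2 enrichment does not recover exactly the ",
      "planted pathway terms; adjust the planted (k, K) design",
      call. = FALSE
    )
  }
  stage2_genes <- genes_of(stage2)

  ## ---- interaction network: hubs, periphery, one isolate ----------------
  nodes <- stage2_genes$symbol
  if (length(nodes) < config$hub_count + 3) {
    stop(sprintf(
      "simulate_bundle: %d stage-2 genes cannot host %d hubs plus an isolate and at least two peripheral nodes",
      length(nodes), config$hub_count
    ), call. = FALSE)
  }
  hubs <- sort(sample(nodes, config$hub_count))
  isolate <- sample(setdiff(nodes, hubs), 1)
  periphery <- setdiff(nodes, c(hubs, isolate))

  planted_edges <- dplyr::bind_rows(
    # hubs pairwise connected
    if (length(hubs) > 1) {
      hp <- utils::combn(hubs, 2)
      tibble::tibble(gene_a = hp[1, ], gene_b = hp[2, ])
    },
    # every hub connected to every peripheral node
    tidyr::expand_grid(gene_a = hubs, gene_b = periphery)
  )
  planted_edges$confidence <- round(stats::runif(
    nrow(planted_edges),
    config$planted_confidence[1], config$planted_confidence[2]
  ), 3)

  # decoy edges: sub-threshold pairs over non-hub genome nodes (isolate
  # included, so it carries links that the confidence screen removes)
  decoy_pool <- c(setdiff(genome, hubs))
  da <- sample(decoy_pool, config$decoy_edge_count, replace = TRUE)
  db_ <- sample(decoy_pool, config$decoy_edge_count, replace = TRUE)
  decoy_edges <- tibble::tibble(
    gene_a = c(da, isolate, isolate),
    gene_b = c(db_, sample(periphery, 2)),
    confidence = round(stats::runif(
      config$decoy_edge_count + 2,
      config$decoy_confidence[1], config$decoy_confidence[2]
    ), 3)
  )
  edge_tbl <- interaction_table(dplyr::bind_rows(planted_edges, decoy_edges))

  net <- build_network(stage2_genes, edge_tbl, min_confidence = 0.900)
  iso_found <- isolated_nodes(net)
  if (!identical(sort(iso_found$symbol), sort(isolate))) {
    stop("simulate_bundle: planted isolate not recovered as the sole isolate",
      call. = FALSE
    )
  }
  pruned <- remove_nodes(net, iso_found)
  report <- centrality(pruned)
  key <- select_key_nodes(report)
  if (!setequal(key$symbol, hubs)) {
    stop(
      "simulate_bundle: key-node selection does not recover exactly the ",
      "planted hubs under the dual mean-threshold rule",
      call. = FALSE
    )
  }

  ## ---- final gene list and drug catalog ---------------------------------
  anchor_genes <- bp$overlaps[[config$bp_planted$term[1]]]
  final_genes <- augment_with_anchor(
    key,
    gene_set(anchor_genes, label = config$bp_planted$term[1])
  )

  whitelist <- default_status_whitelist()
  badlist <- c("preclinical", "discontinued", "suspended", "no development reported")
  blacklist <- default_mechanism_blacklist()
  off_target_pool <- setdiff(genome, final_genes$symbol)

  pick_targets <- function(pool) {
    sort(sample(pool, min(sample(1:3, 1), length(pool))))
  }
  drug_rows <- list()
  idx <- 0
  add_drug <- function(kind, target_pool, status, detail, class) {
    idx <<- idx + 1
    drug_rows[[idx]] <<- tibble::tibble(
      name = sprintf("syn_drug_%03d", idx),
      targets = paste(pick_targets(target_pool), collapse = ";"),
      global_status = status,
      mechanism_class = class,
      has_trial_detail = detail,
      planted_kind = kind
    )
  }
  for (cls in names(config$eligible_classes)) {
    for (j in seq_len(config$eligible_classes[[cls]])) {
      add_drug("eligible", final_genes$symbol, sample(whitelist, 1), TRUE, cls)
    }
  }
  for (j in seq_len(config$n_bad_status)) {
    add_drug(
      "bad_status", final_genes$symbol, sample(badlist, 1),
      sample(c(TRUE, FALSE), 1), sample(names(config$eligible_classes), 1)
    )
  }
  for (j in seq_len(config$n_no_detail)) {
    add_drug(
      "no_detail", final_genes$symbol, sample(whitelist, 1), FALSE,
      sample(names(config$eligible_classes), 1)
    )
  }
  for (j in seq_len(config$n_blacklisted)) {
    add_drug(
      "blacklisted", final_genes$symbol, sample(whitelist, 1), TRUE,
      sample(blacklist, 1)
    )
  }
  for (j in seq_len(config$n_off_target)) {
    add_drug(
      "off_target", off_target_pool, sample(c(whitelist, badlist), 1),
      sample(c(TRUE, FALSE), 1), sample(names(config$eligible_classes), 1)
    )
  }
  drug_tbl <- dplyr::bind_rows(drug_rows)
  # shuffle so planted kinds are not positionally encoded in the catalog
  drug_tbl <- drug_tbl[sample(nrow(drug_tbl)), ]
  catalog <- drug_catalog(drug_tbl[, setdiff(names(drug_tbl), "planted_kind")])

  funnel <- drug_funnel(catalog, final_genes)
  eligible_names <- sort(drug_tbl$name[drug_tbl$planted_kind == "eligible"])
  if (!setequal(funnel$drugs$name, eligible_names)) {
    stop("simulate_bundle: drug funnel survivors differ from the planted eligible drugs",
      call. = FALSE
    )
  }

  ## ---- write bundle ------------------------------------------------------
  paths <- list(
    documents = file.path(dir, "documents.tsv"),
    links = file.path(dir, "links.tsv"),
    bp_gmt = file.path(dir, "bp.gmt"),
    pathway_gmt = file.path(dir, "pathway.gmt"),
    interactions = file.path(dir, "interactions.tsv"),
    drugs = file.path(dir, "drugs.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  readr::write_tsv(documents, paths$documents, progress = FALSE)
  readr::write_tsv(link_tbl, paths$links, progress = FALSE)
  write_gmt_file <- function(terms, path) {
    writeLines(
      vapply(
        names(terms),
        function(tn) paste(c(tn, "synthetic", terms[[tn]]), collapse = "\t"),
        character(1)
      ),
      path
    )
  }
  write_gmt_file(bp_terms, paths$bp_gmt)
  write_gmt_file(pathway_terms, paths$pathway_gmt)
  readr::write_tsv(
    tibble::tibble(
      protein1 = edge_tbl$gene_a, protein2 = edge_tbl$gene_b,
      combined_score = edge_tbl$confidence
    ),
    paths$interactions,
    progress = FALSE
  )
  readr::write_tsv(
    dplyr::mutate(
      drug_tbl[, setdiff(names(drug_tbl), "planted_kind")],
      has_trial_detail = ifelse(.data$has_trial_detail, "true", "false")
    ),
    paths$drugs,
    progress = FALSE
  )

  manifest <- list(
    seed = config$seed,
    genome_size = config$genome_size,
    query_terms = config$query_terms,
    query_lists = stats::setNames(query_lists, config$query_terms),
    core_genes = core,
    bp_planted_terms = config$bp_planted$term,
    bp_planted_overlaps = bp$overlaps,
    stage1_genes = stage1_genes$symbol,
    pathway_planted_terms = config$pathway_planted$term,
    pathway_planted_overlaps = path$overlaps,
    stage2_genes = stage2_genes$symbol,
    hub_genes = hubs,
    isolate_gene = isolate,
    anchor_genes = anchor_genes,
    final_genes = final_genes$symbol,
    eligible_drugs = eligible_names,
    eligible_class_tally = as.list(config$eligible_classes),
    funnel_counts = stats::setNames(
      as.list(funnel$stages$n), funnel$stages$stage
    )
  )
  jsonlite::write_json(manifest, paths$manifest,
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(list(paths = paths, manifest = manifest))
}
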