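make_catalog <- function() {
  toy_catalog(tibble::tibble(
    name = c("d_launch", "d_disc", "d_offtarget", "d_nodetail", "d_il6", "d_combo"),
    targets = c("PPARG", "PPARG", "TP53", "LPL;INS", "IL6", "ADRB1;SLC2A4"),
    status = c(
      "launched", "discontinued", "launched",
      "Phase II Clinical Trial", "registered", "launched"
    ),
    class = c(
      "ppar-gamma agonist", "ppar-gamma agonist", "other",
      "lipase clearing factor stimulant", "interleukin-6 antagonist", "other"
    ),
    detail = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
  ))
}

test_that("target matching keeps catalog order and requires at least one hit", {
  cat <- make_catalog()
  hits <- match_drugs(cat, c("PPARG", "LPL"))
  expect_equal(hits$name, c("d_launch", "d_disc", "d_nodetail"))
  expect_equal(nrow(match_drugs(cat, character(0))), 0)
  # combination drugs match through any component target
  expect_true("d_combo" %in% match_drugs(cat, "SLC2A4")$name)
})

test_that("status, detail, and mechanism filters behave as declared", {
  cat <- make_catalog()
  expect_false("d_disc" %in% filter_status(cat)$name)
  expect_true("d_launch" %in% filter_status(cat)$name)
  # status tokens matched case-insensitively after trimming
  expect_true("d_nodetail" %in% filter_status(cat)$name)
  expect_error(filter_status(cat, character(0)), "nonempty")

  expect_false("d_nodetail" %in% filter_detail(cat)$name)
  expect_true("d_launch" %in% filter_detail(cat)$name)

  expect_false("d_il6" %in% filter_mechanism(cat)$name)
  expect_true("d_launch" %in% filter_mechanism(cat)$name)
  expect_equal(filter_mechanism(cat, character(0))$name, cat$name) # identity
})

test_that("filters are idempotent, order-preserving, and commute", {
  cat <- make_catalog()
  f1 <- function(x) filter_status(x)
  f2 <- function(x) filter_detail(x)
  f3 <- function(x) filter_mechanism(x)
  expect_equal(f1(f1(cat))$name, f1(cat)$name)
  expect_equal(f2(f2(cat))$name, f2(cat)$name)
  expect_equal(f3(f3(cat))$name, f3(cat)$name)
  orders <- list(
    function(x) f3(f2(f1(x))), function(x) f1(f3(f2(x))),
    function(x) f2(f1(f3(x)))
  )
  results <- lapply(orders, function(f) f(cat)$name)
  for (r in results[-1]) expect_equal(r, results[[1]])
})

test_that("class tabulation counts every surviving drug exactly once", {
  cat <- make_catalog()
  expect_equal(nrow(tabulate_classes(cat[0, ])), 0)
  tally <- tabulate_classes(cat)
  expect_equal(sum(tally$n_drugs), nrow(cat))
  expect_equal(tally$n_drugs[tally$mechanism_class == "ppar-gamma agonist"], 2L)
})

test_that("funnel counts are non-increasing and survivors match the planted catalog", {
  tmp <- withr::local_tempdir()
  b <- simulate_bundle(generator_config(seed = 19), dir = tmp)
  cat <- read_drug_catalog(b$paths$drugs)
  funnel <- drug_funnel(cat, gene_set(b$manifest$final_genes))
  expect_true(all(diff(funnel$stages$n) <= 0))
  expect_equal(
    as.list(setNames(funnel$stages$n, funnel$stages$stage)),
    b$manifest$funnel_counts
  )
  expect_setequal(funnel$drugs$name, b$manifest$eligible_drugs)
  expect_equal(sum(funnel$class_tally$n_drugs), funnel$stages$n[4])
  # planted class composition is recovered
  want <- unlist(b$manifest$eligible_class_tally)
  got <- setNames(funnel$class_tally$n_drugs, funnel$class_tally$mechanism_class)
  expect_equal(got[sort(names(want))], want[sort(names(want))])
})

test_that("catalog ingest enforces the declared vocabulary and target contract", {
  expect_error(
    toy_catalog(tibble::tibble(
      name = "x", targets = "A", status = "imaginary phase",
      class = "other", detail = TRUE
    )),
    "unknown status"
  )
  expect_error(
    toy_catalog(tibble::tibble(
      name = "x", targets = "", status = "launched", class = "other", detail = TRUE
    )),
    "at least one target"
  )
  expect_error(
    toy_catalog(tibble::tibble(
      name = c("x", "x"), targets = "A", status = "launched",
      class = "other", detail = TRUE
    )),
    "duplicate"
  )
})
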