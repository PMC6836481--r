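Package: browningscreen
Title: In Silico Drug Repositioning Pipeline for White Fat Browning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of an in-silico drug
    repositioning cascade for the browning of white adipose tissue:
    literature-based gene extraction and query intersection, two-stage
    gene-set enrichment (biological process, then pathway) with a
    log-space hypergeometric upper-tail statistic and multiple-testing
    correction, a high-confidence protein-protein interaction network
    with degree/betweenness key-node selection, anchor-set augmentation
    of the key genes, and a drug-target screening funnel (status
    whitelist, development-detail filter, mechanism blacklist, class
    tabulation). Ships a synthetic-data generator that plants ground
    truth in all four pipeline inputs so every stage is testable offline,
    plus the published candidate-gene tables as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
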