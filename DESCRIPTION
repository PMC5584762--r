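Package: essnet
Title: Essential-Gene Classification from Network-Neighborhood Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for classifying essential versus non-essential
    genes from a protein-protein interaction network and annotation gene sets.
    Each gene is encoded as a vector of -log10 hypergeometric enrichment scores
    of its network neighborhood against GO term and KEGG pathway gene sets;
    features are ranked by maximum-relevance-minimum-redundancy (mRMR) mutual
    information; an optimal feature prefix is chosen by incremental feature
    selection (IFS) under cross-validated support-vector-machine performance,
    with Matthews-correlation-centric evaluation suited to the strong class
    imbalance of essentiality data. A synthetic-data module generates networks
    and annotation collections with planted enrichment signal so the whole
    pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vctrs
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
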