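bg10 <- structure(list(universe = paste0("g", 1:10), N = 10L),
                  class = "ess_background")

test_that("neighbourhoods contain the gene, its partners, and respect the universe", {
  net <- tiny_network()
  bg <- make_background(net)
  expect_setequal(gene_neighborhood(net, "gA", bg), c("gA", "gB", "gC"))
  # isolated gene: singleton neighbourhood
  expect_equal(gene_neighborhood(net, "gE", bg), "gE")
  # universe restriction removes out-of-background neighbours
  bg_small <- make_background(
    NULL, tibble::tibble(members = list(c("gA", "gB", "gC")))
  )
  expect_setequal(gene_neighborhood(net, "gA", bg_small), c("gA", "gB", "gC"))
  bg_tiny <- structure(list(universe = c("gA", "gB"), N = 2L),
                       class = "ess_background")
  expect_setequal(gene_neighborhood(net, "gA", bg_tiny), c("gA", "gB"))
  expect_error(gene_neighborhood(net, "gZ", bg), "not in the background")
})

test_that("enrichment score reproduces the hand-enumerated hypergeometric tail", {
  # N=10, M=4, n=3, m=2: p = (C(4,2) C(6,1) + C(4,3) C(6,0)) / C(10,3) = 1/3
  nbhd <- c("g1", "g2", "g3")
  term <- c("g1", "g2", "g4", "g5")
  s <- enrichment_score(nbhd, term, bg10)
  expect_equal(s, -log10(1 / 3), tolerance = 1e-12)
  expect_equal(s, 0.4771213, tolerance = 1e-6)

  # m = 0: the full tail sums to 1, score 0
  expect_equal(enrichment_score("g1", c("g2", "g3"), bg10), 0)
  # term = universe = neighbourhood: p = 1, score 0
  bg3 <- structure(list(universe = paste0("g", 1:3), N = 3L),
                   class = "ess_background")
  expect_equal(enrichment_score(paste0("g", 1:3), paste0("g", 1:3), bg3), 0)
})

test_that("enrichment score matches exhaustive enumeration on random instances", {
  withr::with_seed(7, {
    for (i in 1:200) {
      N <- sample(2:50, 1)
      M <- sample.int(N, 1)
      n <- sample.int(N, 1)
      m <- sample.int(min(n, M) + 1, 1) - 1L
      p_ref <- enum_hyper_tail(m, M, n, N)
      s <- essnet:::hyper_score(m, M, n, N)
      expect_equal(10^(-s), p_ref, tolerance = 1e-9,
                   label = sprintf("p for N=%d M=%d n=%d m=%d", N, M, n, m))
    }
  })
})

test_that("score is monotone in the overlap and bounded by the cap", {
  N <- 40; M <- 12; n <- 9
  s <- essnet:::hyper_score(0:9, M, n, N)
  expect_true(all(diff(s) >= 0))
  expect_true(all(s >= 0 & s <= 320))
  expect_equal(s[1], 0)
  # p-underflow clamps at the cap
  expect_equal(essnet:::hyper_score(2000, 2000, 2000, 1e6), 320)
  expect_error(essnet:::hyper_score(1, 5, 12, 10), "inconsistent background")
})

test_that("encoded matrices order GO features before KEGG and preserve rows", {
  net <- tiny_network()
  gs <- tibble::tibble(
    term_id = c("hsa00001", "GO:2", "GO:1"),
    term_name = c("p", "q", "r"),
    namespace = c("KEGG", "GO-CC", "GO-BP"),
    members = list(c("gB", "gC"), c("gC", "gD"), c("gA", "gB")),
    size = c(2L, 2L, 2L)
  )
  fm <- encode_genes(net, c("gA", "gB"), gs)
  expect_s3_class(fm, "ess_features")
  expect_equal(names(fm), c("gene", "GO:1", "GO:2", "hsa00001"))
  expect_equal(feature_info(fm)$namespace, c("GO-BP", "GO-CC", "KEGG"))

  # row order tracks input gene order exactly
  fm2 <- encode_genes(net, c("gB", "gA"), gs)
  expect_equal(as.matrix(fm2[2:1, -1]), as.matrix(fm[, -1]),
               ignore_attr = TRUE)

  # isolated gene with no term containing it: all-zero row
  fm3 <- encode_genes(net, "gE", gs)
  expect_true(all(as.matrix(fm3[, -1]) == 0))

  # every entry equals the directly computed score
  bg <- make_background(net, gs)
  expect_equal(
    fm$`GO:1`[1],
    enrichment_score(gene_neighborhood(net, "gA", bg), c("gA", "gB"), bg)
  )
})

test_that("availability filter drops exactly the genes absent from the network", {
  net <- tiny_network()
  labels <- tibble::tibble(
    gene = c("gA", "gB", "missing1", "gC", "missing2"),
    label = factor(c("positive", "positive", "positive",
                     "negative", "negative"),
                   levels = c("negative", "positive"))
  )
  expect_message(res <- filter_unencodable(labels, net), "dropped 2")
  expect_equal(res$kept$gene, c("gA", "gB", "gC"))
  expect_equal(res$dropped$gene, c("missing1", "missing2"))
  expect_true(all(res$dropped$reason == "absent_from_network"))

  # all present: identity
  res2 <- filter_unencodable(labels[c(1, 2, 4), ], net)
  expect_equal(res2$kept, labels[c(1, 2, 4), ])
  expect_equal(nrow(res2$dropped), 0L)
})

test_that("positive genes score higher on planted terms than negatives", {
  ds <- generate_dataset(small_config(seed = 3))
  flt <- filter_unencodable(ds$labels, ds$network)
  fm <- encode_genes(ds$network, flt$kept, ds$gene_sets)
  info <- ds$truth$informative_terms
  m <- as.matrix(fm[, info])
  pos <- fm$gene %in% flt$kept$gene[flt$kept$label == "positive"]
  expect_gt(mean(m[pos, ]), mean(m[!pos, ]))
})
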