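# Separable two-feature toy data used by several CV tests.
toy_data <- function(n_pos = 20, n_neg = 80, seed = 4, shift = 4) {
  withr::with_seed(seed, {
    n <- n_pos + n_neg
    X <- matrix(rnorm(n * 4), n, 4)
    X[seq_len(n_pos), 1:2] <- X[seq_len(n_pos), 1:2] + shift
    colnames(X) <- paste0("F", 1:4)
    list(
      features = dplyr::bind_cols(
        tibble::tibble(gene = paste0("g", seq_len(n))),
        tibble::as_tibble(X)
      ),
      labels = tibble::tibble(
        gene = paste0("g", seq_len(n)),
        label = factor(rep(c("positive", "negative"), c(n_pos, n_neg)),
                       levels = c("negative", "positive"))
      )
    )
  })
}

test_that("stratified folds preserve the class ratio and the seed", {
  y <- rep(c("positive", "negative"), c(20, 80))
  f <- stratified_folds(y, n_folds = 10, seed = 1)
  tab <- table(y, f)
  expect_true(all(tab["positive", ] == 2))
  expect_true(all(tab["negative", ] == 8))
  expect_identical(stratified_folds(y, seed = 1), f)
  expect_false(identical(as.integer(stratified_folds(y, seed = 2)),
                         as.integer(f)))

  # gold-standard scale: 205/830 split into folds of 20-21 and 83
  y2 <- rep(c("positive", "negative"), c(205, 830))
  f2 <- stratified_folds(y2, seed = 7)
  tab2 <- table(y2, f2)
  expect_true(all(tab2["positive", ] %in% 20:21))
  expect_true(all(tab2["negative", ] == 83))

  expect_error(stratified_folds(rep(c("positive", "negative"), c(5, 95))),
               "fewer members")
})

test_that("cross-validation is perfect on separable data and conserves counts", {
  td <- toy_data()
  res <- cross_validate(td$features, td$labels, c("F1", "F2"), seed = 1)
  expect_equal(res$MCC, 1)
  expect_equal(res$TP + res$TN + res$FP + res$FN, 100)

  # uninformative features: counts still conserved
  res2 <- cross_validate(td$features, td$labels, c("F3", "F4"), seed = 1)
  expect_equal(res2$TP + res2$TN + res2$FP + res2$FN, 100)
})

test_that("permuted labels yield null-level MCC", {
  withr::with_seed(31, {
    n <- 1000
    X <- matrix(rnorm(n * 10), n, 10)
    colnames(X) <- paste0("F", 1:10)
    feats <- dplyr::bind_cols(tibble::tibble(gene = paste0("g", 1:n)),
                              tibble::as_tibble(X))
    y <- sample(rep(c("positive", "negative"), c(200, 800)))
    res <- cross_validate(feats, y, paste0("F", 1:10), seed = 1)
    expect_lt(abs(res$MCC), 0.15)
  })
})

test_that("a training split holding one class is a hard error", {
  td <- toy_data(n_pos = 20, n_neg = 80)
  # rig a fold assignment putting every positive in fold 1's training only
  folds <- c(rep(2, 20), rep(1, 40), rep(2, 40))
  expect_error(
    cross_validate(td$features, td$labels, "F1", folds = folds),
    "single class|degenerate"
  )
})

test_that("IFS sweeps prefixes on one shared fold assignment, deterministically", {
  td <- toy_data(n_pos = 30, n_neg = 70)
  rk <- mrmr_rank(td$features, td$labels)
  folds <- stratified_folds(td$labels, seed = 2)
  ifs <- run_ifs(td$features, td$labels, rk, k_min = 1, k_max = 4,
                 folds = folds)
  expect_equal(nrow(ifs$records), 4L)
  expect_equal(ifs$records$k, 1:4)
  expect_identical(as.integer(ifs$folds), as.integer(folds))
  # optimal k attains the maximum MCC, smallest such k on ties
  expect_equal(ifs$optimal_k,
               min(ifs$records$k[ifs$records$MCC == max(ifs$records$MCC)]))

  # single-point sweep
  one <- run_ifs(td$features, td$labels, rk, k_min = 2, k_max = 2,
                 folds = folds)
  expect_equal(nrow(one$records), 1L)
  expect_equal(one$optimal_k, 2L)

  # bit-identical reproduction under identical inputs and seed
  ifs2 <- run_ifs(td$features, td$labels, rk, k_min = 1, k_max = 4,
                  folds = stratified_folds(td$labels, seed = 2))
  expect_identical(ifs$records, ifs2$records)
  expect_identical(ifs$optimal_k, ifs2$optimal_k)

  expect_error(run_ifs(td$features, td$labels, rk, k_min = 1, k_max = 10),
               "exceeds")
})

test_that("the final model refits cleanly, round-trips, and scores new genes", {
  td <- toy_data(n_pos = 30, n_neg = 70)
  rk <- mrmr_rank(td$features, td$labels)
  folds <- stratified_folds(td$labels, seed = 2)
  ifs <- run_ifs(td$features, td$labels, rk, k_min = 1, k_max = 4,
                 folds = folds)
  sub <- head(ifs$feature_order, ifs$optimal_k)
  mod <- train_final(td$features, td$labels, sub)

  # training-set MCC is at least the CV MCC (optimistic bias direction)
  pr <- predict(mod, td$features)
  cc <- confusion_counts(td$labels$label, pr$label)
  train_mcc <- compute_metrics(cc$TP, cc$TN, cc$FP, cc$FN)$MCC
  expect_gte(train_mcc, max(ifs$records$MCC))

  # save -> load -> predict round trip
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(mod, path)
  pr2 <- predict(readRDS(path), td$features)
  expect_identical(pr, pr2)

  # a row identical to a training positive predicts positive
  pos_row <- td$features[1, ]
  pos_row$gene <- "query"
  expect_equal(as.character(predict(mod, pos_row)$label), "positive")

  # empty unlabeled set: empty, well-typed output
  empty <- predict(mod, td$features[0, ])
  expect_equal(nrow(empty), 0L)
  expect_named(empty, c("gene", "label", "decision"))

  # feature-order mismatch is an error
  expect_error(predict(mod, td$features[, c("gene", "F3", "F4")]),
               "lacks model feature")
})

test_that("IFS-selected features beat size-matched random subsets across seeds", {
  # paired parameter-recovery comparison over 10 generator seeds on a
  # reduced configuration: the optimal model must recover the planted signal
  # (high CV MCC) and outperform a model with the same number of randomly
  # chosen features under the identical fold assignment
  res <- vapply(1:10, function(s) {
    cfg <- synthetic_config(
      n_genes = 200, n_pos = 40, n_neg = 160,
      n_go_terms = 30, n_kegg_terms = 8, term_size_range = c(6, 12),
      n_informative_terms = 6, p_signal = 0.5, p_background = 0.015,
      seed = s
    )
    ds <- generate_dataset(cfg)
    flt <- filter_unencodable(ds$labels, ds$network)
    fm <- encode_genes(ds$network, flt$kept, ds$gene_sets)
    rk <- mrmr_rank(fm, flt$kept)
    folds <- stratified_folds(flt$kept, seed = 1)
    ifs <- run_ifs(fm, flt$kept, rk, k_min = 2, k_max = 16, folds = folds)
    rnd <- withr::with_seed(1000 + s,
                            sample(setdiff(names(fm), "gene"), ifs$optimal_k))
    c(opt = max(ifs$records$MCC),
      rnd = cross_validate(fm, flt$kept, rnd, folds = folds)$MCC)
  }, c(opt = 0, rnd = 0))
  expect_gte(mean(res["opt", ]), 0.9)
  expect_true(all(res["opt", ] > res["rnd", ]))
})

test_that("held-out genes from the positive mechanism are mostly predicted positive", {
  # hold out part of the positive class before training, then score the
  # held-out genes as if unlabeled: the planted wiring should be recognised
  cfg2 <- synthetic_config(
    n_genes = 300, n_pos = 50, n_neg = 200,
    n_go_terms = 40, n_kegg_terms = 10,
    term_size_range = c(8, 16), n_informative_terms = 8,
    p_signal = 0.5, p_background = 0.01, seed = 12
  )
  ds2 <- generate_dataset(cfg2)
  flt2 <- filter_unencodable(ds2$labels, ds2$network)
  fm2 <- encode_genes(ds2$network, flt2$kept, ds2$gene_sets,
                      background = make_background(ds2$network, ds2$gene_sets))
  rk2 <- mrmr_rank(fm2, flt2$kept)
  # hold out 20% of each class before training
  withr::with_seed(1, {
    pos_all <- flt2$kept$gene[flt2$kept$label == "positive"]
    hold_pos <- sample(pos_all, 10)
  })
  train_lab <- flt2$kept[!flt2$kept$gene %in% hold_pos, ]
  fm_train <- fm2[fm2$gene %in% train_lab$gene, ]
  mod2 <- train_final(fm_train, train_lab, head(rk2$ranking$term_id, 16))
  pr <- predict(mod2, fm2[fm2$gene %in% hold_pos, ])
  expect_gte(mean(pr$label == "positive"), 0.8)
})
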