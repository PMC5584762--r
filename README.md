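# essnet

Classify essential versus non-essential genes from the functional context of
their protein–protein interaction (PPI) neighbourhoods.

Essential genes are those a cell cannot survive without, and screens that
label them (e.g. in human cell lines) leave two questions open: which
functional categories distinguish essential genes, and can a model predict
essentiality for unlabeled genes? `essnet` implements a complete, tested
pipeline for both:

1. **Enrichment encoding.** Each gene *g* is represented by the functional
   profile of its network neighbourhood *G(g)* (the gene plus its direct
   interaction partners). For every annotation gene set *T* (GO term or KEGG
   pathway, |T| = M) the feature is the upper-tail hypergeometric
   enrichment score

   S(g, T) = −log₁₀ Σₖ₌ₘⁿ C(M, k) · C(N−M, n−k) / C(N, n)

   where N is the background gene count, n = |G(g)| and
   m = |G(g) ∩ T|. Genes without a network presence carry no usable
   encoding and are filtered out first.
2. **mRMR ranking.** Features are ranked by maximum relevance, minimum
   redundancy: greedily append the feature maximising D − R, with relevance
   D = I(f, class) and redundancy R the mean mutual information to the
   already-selected features. The relevance-only ordering (MaxRel list) is
   produced alongside.
3. **Incremental feature selection (IFS).** Nested prefixes of the mRMR list
   (k = 5..500 by default) are each evaluated by stratified 10-fold
   cross-validation of a linear SVM, pooling held-out confusion counts. The
   smallest k attaining the maximum Matthews correlation coefficient (MCC)
   defines the optimal feature set; MCC is the headline metric because the
   classes are imbalanced roughly 1:4.
4. **Prediction.** The final model, trained on all labeled genes with the
   optimal features, scores unlabeled genes with a signed decision value.

A synthetic-data module generates networks, annotation collections and label
lists with *planted* enrichment signal, so the whole pipeline can be
exercised, and its parameter recovery measured, without any database
downloads.

## Worked example

```r
library(essnet)

# a synthetic benchmark: 1000 genes, 200 essential / 800 non-essential,
# 550 annotation terms of which 20 carry planted signal
ds  <- generate_dataset(synthetic_config(seed = 1))
flt <- filter_unencodable(ds$labels, ds$network)
fm  <- encode_genes(ds$network, flt$kept, ds$gene_sets)
rk  <- mrmr_rank(fm, flt$kept)
ifs <- run_ifs(fm, flt$kept, rk, k_min = 5, k_max = 500,
               folds = stratified_folds(flt$kept, seed = 1))
ifs
#> <ess_ifs> 496 feature-count records; optimal k = 61 (MCC = 0.987)

glance(ifs)
#> # A tibble: 1 × 6
#>   n_records optimal_k    SN    SP   ACC   MCC
#>       <int>     <int> <dbl> <dbl> <dbl> <dbl>
#> 1       496        61  0.98     1 0.996 0.987
```

The IFS sweep evaluated 496 nested feature sets; cross-validated MCC peaks
at 0.987 using the top 61 mRMR-ranked features, which recover 196 of the
200 essential genes with zero false positives (SP = 1). Of the 20
planted informative terms, 18 sit in the MaxRel top 40, so the ranking
recovered nearly all of the ground truth. `autoplot(ifs)` draws the IFS
curve with the optimum marked, and `tidy(ifs)` returns the per-k record
table. The final model then scores genes:

```r
mod <- train_final(fm, flt$kept, head(ifs$feature_order, ifs$optimal_k))
predict(mod, fm[1:3, ])
#> # A tibble: 3 × 3
#>   gene  label    decision
#>   <chr> <fct>       <dbl>
#> 1 g0836 positive     4.79
#> 2 g0679 positive     3.33
#> 3 g0129 positive     3.96
```

Real data drop in the same way: `read_network()` takes a STRING-style TSV
edge list, `read_gene_sets()` a GMT file per namespace, and `read_labels()`
plain gene lists.

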