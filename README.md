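# cdaboost

Predicting circRNA-disease associations from heterogeneous similarity
networks with gradient-boosted trees and leaf-membership embeddings.

Circular RNAs (circRNAs) are implicated in many diseases, but confirmed
circRNA-disease associations are scarce because each one takes laboratory
work. Given a binary association matrix **A** (circRNA x disease), an
optional circRNA expression-profile matrix, and an optional precomputed
disease semantic-similarity matrix, `cdaboost` ranks the unknown pairs so
validation effort can be prioritized. It is aimed at computational
biologists working on noncoding-RNA disease prioritization.

## Method

1. **Integrated similarities.** circRNA similarity = binarized Pearson
   expression similarity (cutoff 0.4), falling back where it is zero to the
   Gaussian interaction profile (GIP) kernel
   `K(i,j) = exp(-gamma * ||y_i - y_j||^2)` on the rows of A, with
   `gamma = gamma' / ((1/n) sum_i ||y_i||^2)`. Disease similarity =
   semantic similarity with the analogous GIP fallback on the columns of A.
2. **Per-pair features.** For each node: mean + 10-bin histogram of its
   similarity scores; neighbour count and degree/closeness/betweenness
   centrality in the graph thresholded at the mean similarity; mean +
   histogram of its top-10 most similar neighbours. Plus rank-8
   non-negative matrix factorization (NMF) factors of A (`A ~ W H`): the
   circRNA's row of W and the disease's column of H.
3. **Leaf embeddings.** A first boosted-tree ensemble is fit on these
   features; each sample is re-encoded by which leaf it falls into in each
   tree (one-of-K per tree), and a final boosted classifier is trained on
   the original features stacked with this sparse embedding.
4. **Evaluation.** Balanced negative sampling (as many unknown pairs as
   known positives), stratified k-fold cross-validation, per-fold and mean
   ACC / AUC / PRE / REC / F1. By default the test fold's associations are
   masked out of A before the GIP/NMF features are computed (leakage-safe);
   `--paper-mode` computes features once on the full matrix.

A synthetic generator with planted block structure
(`generate_dataset()`) makes the whole pipeline runnable with no downloads.

## Worked example

```r
library(cdaboost)

dataset <- generate_dataset(synthetic_config(seed = 42))   # 200 circRNAs x 60 diseases
report <- cross_validate(dataset$assoc, dataset$expr, dataset$dsim,
                         k = 5, seed = 42)
report
#> 5-fold cross-validation
#>  fold    ACC    AUC    PRE    REC     F1
#>     1 0.7339 0.7839 0.8030 0.6199 0.6997
#>     2 0.7164 0.8243 0.7984 0.5789 0.6712
#>     3 0.7018 0.8065 0.8053 0.5322 0.6408
#>     4 0.7135 0.7693 0.8120 0.5556 0.6597
#>     5 0.7912 0.8326 0.8278 0.7353 0.7788
#> mean:
#>    ACC    AUC    PRE    REC     F1
#> 0.7313 0.8033 0.8093 0.6044 0.6900
```

Mean AUC ~0.80 says the model recovers the planted circRNA-group x
disease-group association blocks from the leakage-safe protocol at this
scale; shuffling the labels drops it to ~0.49 (chance). Scoring unknown
pairs:

```r
top <- train_final_and_score(dataset$assoc, dataset$expr, dataset$dsim,
                             seed = 42, top_n = 5)
#      circRNA    disease     score
#   (five highest-scoring unknown pairs, probabilities in [0, 1])
```

## Command line

A thin Rscript wrapper lives at `inst/cli/cdaboost.R`
(`system.file("cli", "cdaboost.R", package = "cdaboost")`):

```sh
Rscript inst/cli/cdaboost.R simulate --out data --seed 7
Rscript inst/cli/cdaboost.R cv --assoc data/association.tsv \
    --expr data/expression.tsv --dsim data/disease_similarity.tsv \
    --out run --folds 5 --seed 7
Rscript inst/cli/cdaboost.R predict --assoc data/association.tsv \
    --expr data/expression.tsv --dsim data/disease_similarity.tsv \
    --out run --score-threshold 0.9 --top 20
```

Every run writes a log of the fully resolved configuration; a flat
`key = value` config file can be passed with `--config`.

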