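# mutclust

Molecular subtyping of tumors from sparse somatic-mutation profiles, for
computational biologists who have a binary tumors-by-genes alteration
matrix and a gene interaction network and want reproducible subtypes,
per-subtype gene signatures, and a classifier for new tumors.

## What it does

Raw somatic profiles are too sparse to cluster: tumors driven by the same
pathway may share no mutated gene. `mutclust` runs a five-stage pipeline:

1. **Network propagation.** A random walk with restart smooths each
   profile over the interactome,
   D<sub>i+1</sub> = α·D<sub>i</sub>·A + (1−α)·D<sub>0</sub>,
   with A the degree-normalized adjacency (columns sum to 1), α = 0.4 and
   convergence at Frobenius norm < 10⁻⁶. The closed-form fixed point
   (1−α)·D₀·(I−αA)⁻¹ is implemented as an exact oracle.
2. **Deep embedded clustering.** A stacked auto-encoder (greedy layerwise
   pretraining with dropout) embeds the smoothed profiles; k-means
   initializes k centroids; self-training then minimizes the KL divergence
   between the Student-t soft assignment Q and its sharpened target P,
   updating encoder and centroids by seeded SGD until fewer than 0.1% of
   labels change.
3. **Cluster evaluation and k-selection.** Agreement with a reference
   partition via cluster-wise PPV/SN/ACC, the maximum-matching ratio MMR,
   Precision⁺/Recall⁺/F⁺ from maximum-cardinality matching on the
   neighborhood-affinity graph (NA = |p∩c|²/(|p||c|)), and AUMF — the area
   under the MMR+F⁺ curve over the affinity threshold θ∈[0,1], in [0,2].
   `select_k()` picks the AUMF-maximizing k. Silhouette is reported too.
4. **Gene signatures.** Per subtype, one-sided Fisher's exact test for
   mutation enrichment on the raw binary matrix; top 50 genes with
   p < 0.05.
5. **Supervised prediction.** Repeated stratified tenfold cross-validation
   of five classifiers (random forest, SVM, MLP, kNN, naive Bayes) with a
   multiclass confusion/ROC suite (per-class, micro- and macro-averaged
   AUC) and random-forest Gini-importance gene selection (> 0.01).

A synthetic-cohort generator with planted, network-adjacent driver modules
makes the whole pipeline testable end to end without external data.

## Worked example

```r
library(mutclust)

cohort   <- simulate_cohort(sim_config(seed = 1))   # 240 tumors x 500 genes, 4 planted subtypes
smoothed <- propagate(cohort$mutations, cohort$network)

runner <- function(X, k) fit_dec(X, k, config = sae_config(seed = 1))$partition
sel <- select_k(smoothed$matrix, cohort$truth_labels, 2:6, runner = runner)
sel$table
#>   k      AUMF       ACC       PPV        SN silhouette
#> 1 2 0.7439479 0.7331439 0.5375000 1.0000000 0.07586574
#> 2 3 1.2997173 0.8832154 0.7833333 0.9958333 0.11776110
#> 3 4 2.0000000 1.0000000 1.0000000 1.0000000 0.16128103
#> 4 5 1.6791667 0.9574271 1.0000000 0.9166667 0.11317041
#> 5 6 1.3200551 0.8827042 1.0000000 0.7791667 0.08248973
sel$best_k
#> [1] 4
```

AUMF reaches its ceiling of 2 exactly at the planted k = 4 — the
discovered and planted partitions coincide, so every matched affinity is 1
— and falls off on either side, more sharply for under-clustering. The
signatures and the classifier close the loop:

```r
labels <- sel$partitions[[as.character(sel$best_k)]]
sigs   <- all_signatures(cohort$mutations, labels)      # planted drivers top each list
report <- cross_validate(smoothed$matrix, labels, cv_config(repeats = 10, seed = 2))
round(c(accuracy = report$accuracy, auc_macro = report$auc_macro), 4)
#> accuracy auc_macro
#>   0.9990    1.0000
```

A thin command-line wrapper over the same functions ships in
`inst/cli/mutclust.R` (subcommands `simulate`, `propagate`, `cluster`,
`select-k`, `evaluate`, `signatures`, `classify`, `importance`,
`pipeline`).

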