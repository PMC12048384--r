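# cbbgwo

Cluster-guided binary grey wolf optimization for tripeptide-based
protein classification.

## What this is for

Multiclass protein-sequence classification — e.g. assigning curated
disease-associated protein sets to their disease class — needs feature
selection: the tripeptide composition (TPC) encoding turns every protein
of length $L$ into the $20^3 = 8000$-dimensional vector of window
frequencies $\alpha_i = D_i/(L-2)$, a space that is wide, sparse and
redundant. `cbbgwo` implements a wrapper selector for this regime:

1. **Mutual information structure.** Features are discretized
   (equal-frequency bins) and the pairwise MI matrix
   $I(f_i; f_j) = H(f_i) + H(f_j) - H(f_i, f_j)$ is computed in bits,
   along with each feature's MI with the class label.
2. **Feature clustering.** Each feature's MI profile (its matrix row) is
   the point fed to Lloyd k-means (Euclidean, best-of-restarts by WCSS),
   partitioning the features into $K \approx \sqrt d$ groups of mutually
   redundant features.
3. **Per-cluster binary grey wolf optimization.** Inside each cluster a
   population of bit vectors searches for the subset minimizing
   $\lambda(1-\mathrm{acc}_{CV}) + (1-\lambda)\,n_{sel}/d$. Wolves move
   by attraction to the three best solutions (alpha, beta, delta): a
   steep sigmoid $1/(1+e^{-10(AD-0.5)})$ of the leader-distance step is
   thresholded into binary steps, OR-ed with the leader bits, and the
   three candidates are combined by a uniform three-way stochastic
   crossover.
4. **Aggregation + One-vs-Rest evaluation.** Per-cluster winners are
   unioned into the final feature set; five classifiers (gradient
   boosting, Gaussian process, linear SVC, logistic regression, SGD) are
   fitted One-vs-Rest on a held-out split, reporting accuracy, macro
   precision/recall/F1 and macro OvR AUC.

A planted-motif synthetic generator (class-specific tripeptides inserted
at a Poisson rate over uniform background) provides exact ground truth
for recovery benchmarking, so the whole pipeline is testable without
external data.

## Worked example

```r
library(cbbgwo)

# synthetic study set: 3 classes, 2 planted tripeptide motifs per class
synth <- generate_synthetic(n_classes = 3, n_per_class = 12,
                            length_range = c(60, 90), motifs_per_class = 2,
                            insertion_rate = 4, seed = 17)
pp    <- preprocess(synth$records)        # length/duplicate/alphabet filters
feats <- encode_dataset(pp$records)       # 36 x 8000 TPC matrix
feats
#> TPC feature matrix: 36 sequences x 8000 tripeptide features
#>   classes: class_1, class_2, class_3
#>   non-zero columns: 2050

res <- cbbgwo_run(feats, config = pipeline_config(master_seed = 7,
                                                  n_restarts = 3, n_iter = 8))
res
#> CB-BGWO selection
#>   retained features: 1457 of 8000
#>   clusters (K):      38
#>   selected features: 543 (6.8% of the full space)

recovery_metrics(res$selected, synth)     # planted-feature recovery
#>     recall  precision
#> 1.00000000 0.01104972

head(rank_selected(res), 3)               # top selected features by label MI
#>   rank feature_index tripeptide relevance_bits cluster_id
#> 1    1          2576        HKS      0.9182958         17
#> 2    2          5391        QLM      0.9182958         23
#> 3    3          5806        RMG      0.9182958         21

xs <- feats$x[, res$selected]
ev <- evaluate_classifiers(xs[res$split$train, ], feats$labels[res$split$train],
                           xs[res$split$test, ],  feats$labels[res$split$test],
                           seed = 3)
ev
#> One-vs-Rest evaluation (macro averages)
#>   gradient_boosting    acc 0.833  prec 0.889  rec 0.833  F1 0.838  AUC 0.917
#>   gaussian_process     acc 0.917  prec 0.933  rec 0.917  F1 0.915  AUC 1.000
#>   linear_svc           acc 1.000  prec 1.000  rec 1.000  F1 1.000  AUC 1.000
#>   logistic_regression  acc 0.917  prec 0.933  rec 0.917  F1 0.915  AUC 1.000
#>   sgd                  acc 0.417  prec 0.455  rec 0.417  F1 0.311  AUC 1.000
```

Reading the output: the selector kept all six planted motifs (recall
1.0; precision is low because fitness-flat bits survive in noise-only
clusters), the top-ranked tripeptides are planted motifs carrying ~0.9
bits of label information each, and the held-out classifiers separate
the classes on the selected columns — except the unregularized-scale SGD
linear model, which underfits this tiny 12-sequence test split (its
ranking scores are still perfect, AUC 1.0); at the default study scale
of 240 sequences it reaches accuracy around 0.8-0.97 depending on seed.

Real data enter through FASTA plus a tab-separated `id<TAB>label` table:

```r
records <- attach_labels(read_fasta("proteins.fasta"),
                         read_label_table("labels.tsv"))
feats <- encode_dataset(preprocess(records)$records)
```

A command-line front end with the same options ships in
`inst/cli/cbbgwo.R`.

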