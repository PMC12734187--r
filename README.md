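# mdignn

Semi-supervised prioritization of cancer driver genes on **directed** gene
regulatory networks. Most graph neural networks for this task symmetrize
the network and discard who regulates whom; `mdignn` keeps direction inside
the convolution operator itself, via the **magnetic Laplacian** — a complex
Hermitian operator whose magnitude encodes connectivity and whose phase
encodes edge direction.

The package is aimed at computational cancer-genomics groups who have (a)
directed regulatory edge lists and/or undirected PPI edge lists, (b)
per-gene multi-omics summaries or per-sample tumor/normal matrices, and
(c) lists of known driver and non-driver genes, and who want calibrated
per-gene driver probabilities plus a ranked list of novel candidates. A
seeded synthetic benchmark generator with planted drivers makes every
stage runnable and testable without any external data.

## The model

For a directed graph with binary asymmetric adjacency `A`:

    S      = (A + Aᵀ) / 2                           symmetrized connectivity
    Θ(q)   = 2πq (A − Aᵀ)                           phase matrix, q ≥ 0
    H(q)   = S ⊙ exp(iΘ(q))                         Hermitian adjacency
    L(q)   = I − D^{−1/2} S D^{−1/2} ⊙ exp(iΘ(q))   normalized magnetic Laplacian

`L(q)` is Hermitian positive-semidefinite with eigenvalues in `[0, 2]`;
`q = 0` recovers the classical normalized Laplacian, while `q = 0.25`
(default) maps every one-way edge to a purely imaginary entry. Stacked
Chebyshev convolution layers

    X(ℓ) = σ( X(ℓ−1) W_self + L̃(q) X(ℓ−1) W_neigh + B ),   L̃ = L − I

with a complex ReLU (`z ↦ z·1[Re z ≥ 0]`) run on node features built from
per-cancer-type mutation rate, tumor−normal differential methylation
(mean of `βᵗ − βⁿ` over matched pairs), mean log2 expression fold change,
ten system-level gene properties, and 16-dimensional node2vec embeddings
(48 + 10 + 16 = 74 columns for a 16-type cohort). The complex output is
unwound into `[Re | Im]`, refined by sequential channel and spatial
attention, and scored by a fully connected sigmoid head. Training is
full-batch Adam with class-weighted cross-entropy, per-epoch edge dropout,
and early stopping on a validation split; evaluation is repeated
stratified 5-fold cross-validation (AUROC, AUPR, accuracy, sensitivity,
specificity, precision, MCC).

See `vignettes/mdignn-methods.Rmd` for assumptions, parameter defaults,
numerical choices, and what the synthetic benchmark does and does not
demonstrate.

## Worked example

Simulate a 200-gene network with 25 planted drivers, featurize, train,
and rank:

```r
library(mdignn)

spec  <- sim_spec(n_genes = 200, n_drivers = 25, n_nondrivers = 60,
                  n_cancer_types = 4, samples_per_type = 20, seed = 42)
graph <- simulate_graph(spec)
truth <- planted_labels(spec)
omics <- simulate_cohort(spec, truth$drivers)

features <- featurize(graph, omics$cohort, omics$sys, walk_config(seed = 42))
labels   <- label_set(truth$drivers, truth$nondrivers, graph)

cfg <- run_config(seed = 42, max_epochs = 300, patience = 30)
fit <- train_mdignn(graph, features, labels, cfg)
ranked <- rank_candidates(fit, graph, features, labels, threshold = 0.9)
head(ranked, 5)
cv <- cross_validate(graph, features, labels, cfg, n_folds = 5, n_repeats = 1)
cv
```

which prints (abridged):

```
<gene_graph> 200 nodes, 1087 directed edges [tags: SIM]
<feature_matrix> 200 genes x 38 features (biological: 12, sys: 10, topological: 16)
<mdignn_fit> stopped at epoch 181 (best validation epoch 151, loss 0.0075)
   gene probability label_status rank candidate novel
1 G0074   0.9999041     positive    1      TRUE FALSE
2 G0041   0.9998472     positive    2      TRUE FALSE
3 G0165   0.9997603     positive    3      TRUE FALSE
<metrics_report> 5 folds x 1 repeats (mean +/- sd)
  auroc        1.0000 +/- 0.0000
  aupr         1.0000 +/- 0.0000
```

At the default planted effect size (`delta = 2`, `rho = 2`) the signal is
strong by design, so cross-validated recovery is essentially perfect; the
companion null configuration (`delta = 0`, `rho = 1`) is exchangeable and
scores at chance. The feature matrix here is 38-wide because the example
cohort has 4 pseudo-cancer-types (3 × 4 + 10 + 16); a 16-type cohort
gives the canonical 74 columns.

Real edge lists enter through `read_edge_list()` / `integrate_sources()`
(confidence thresholds are strict: scores must exceed the cutoff),
cohorts through `read_cohort()`, and a thin CLI wraps the same functions:

```sh
exec/mdignn simulate --out bench/ --seed 1
exec/mdignn evaluate --bench bench/ --cv 5x2 --metrics-out metrics.tsv
exec/mdignn rank     --bench bench/ --threshold 0.9 --out candidates.tsv
```

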