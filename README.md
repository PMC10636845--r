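# tscluster

Two-step clustering of single-cell RNA-seq expression matrices.

Cell clustering in scRNA-seq is hardest at cluster boundaries: transitional
and noisy cells drag down the accuracy of any method that must place every
cell at once. `tscluster` splits the task. It first identifies **core
cells** — cells tightly connected to their neighbours in a weighted
similarity graph, presumed to lie near cluster centers — and clusters only
them; the remaining **non-core cells** are then assigned to the nearest
resulting cluster center, where they cannot distort the cluster structure.
The package targets analysts working with cells × genes expression tables
(FPKM/CPM/UMI) of desk scale — tens to a few thousand cells.

The machinery, in brief:

* **Preprocessing.** Genes detected in < 2% of cells are dropped. A
  *right-skewness coefficient* of the gene maxima,
  `RSC = Σ_{g_i^max ≥ μ}(g_i^max − μ) / (l·μ)` (computed after an IQR outlier
  trim), decides the transform: when `RSC > 0.8` every value becomes
  `log2(v + 1)`, otherwise the matrix is left on the linear scale.
* **Cell graph.** Pairwise similarities in [0, 1] under one of five metrics
  (Euclidean, Manhattan, Pearson, Spearman, shared nearest neighbours;
  Pearson by default). The strongest 25% of edges define the core cells.
* **Random-walk distance.** On the core graph with transition matrix
  `M_ij = w_ij / Deg(i)`, cells are compared by their t-step walk
  probability rows (`t = 4`):
  `d_ij = sqrt( Σ_k (P_ik − P_jk)² / Deg(k) )`.
* **Hierarchical clustering.** Ward-style agglomeration on that distance;
  the number of clusters K maximises the ratio of successive merge costs
  `η_K = (σ_{K−1} − σ_K)/(σ_K − σ_{K+1})` — the level just before a
  disproportionately expensive merge.
* **Assignment.** Cluster centers are per-gene means of core-cell profiles
  (`c_kj = Σ_{c∈χ_k} x_cj / |χ_k|`); each non-core cell takes the label of
  its nearest center, in one pass.
* **Evaluation.** ARI (from the contingency-table formula), NMI, AMI and
  best-matching accuracy against reference labels.
* **Simulation.** A generator of scRNA-like matrices with planted clusters,
  controllable skewness, boundary cells and dropout, so the whole pipeline
  is testable offline.

## Worked example

```r
library(tscluster)

# 300 cells, 3 planted clusters, 20% boundary cells between centroids
sim <- simulate_cells(n_cells = 300, n_genes = 200, k_true = 3,
                      boundary_fraction = 0.2, skew_mode = "uniform",
                      seed = 101)

res <- run_tsc(sim$x)
res
#> TSCResult: 300 cells in 3 clusters (247 core, 53 non-core)
#>   RSC = 0.090, log2(x+1) not applied
#>   metric = pcc, edge_fraction = 0.25, t = 4
#>   cluster sizes: 100 96 104

scores <- clustering_scores(sim$labels, res$labels)
cat(sprintf("ARI %.3f | NMI %.3f | AMI %.3f | Acc %.3f\n",
            scores$ari, scores$nmi, scores$ami, scores$acc))
#> ARI 0.755 | NMI 0.682 | AMI 0.680 | Acc 0.913

core <- names(res$is_core)[res$is_core]
adjusted_rand_index(sim$labels[core], res$labels[core])
#> [1] 0.976
```

The run reads as follows: the uniform-regime fixture is not right-skewed
(RSC 0.09, far below the 0.8 threshold), so no log transform is applied; 53
of the 300 cells — mostly the planted boundary cells — fall below the edge
threshold and are assigned in the second step. The automatically selected
K equals the planted 3. Agreement with the planted labels is near-perfect on
the core cells (ARI 0.976) and lower over all cells (ARI 0.755), because the
boundary cells are genuinely ambiguous — which is precisely the rationale
for clustering the two groups separately.

A thin command-line wrapper over the same functions ships in `inst/cli/tsc`
(subcommands `cluster`, `evaluate`, `simulate`, `sweep`).

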