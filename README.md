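# scphenix

Diffusion-based imputation of dropout noise in single-cell RNA-seq, with the
cell-cell graph built on a **PCA-UMAP manifold**, plus the evaluation
machinery needed to tell good imputation from over-smoothing.

## The problem and the method

Single-cell RNA-seq matrices are riddled with technical zeros (dropouts).
Diffusion-based imputation replaces each cell's profile with a weighted
average over its neighborhood on the expression manifold: from a cell-cell
distance matrix one builds an adaptive Gaussian affinity

    A[i, j] = exp( -( d(i, j) / sigma_i )^decay ),   sigma_i = distance to i's knn-th neighbor,

symmetrizes it (`A + t(A)`), row-normalizes it into a Markov transition
matrix `M`, and imputes with the exponentiated matrix

    D_imputed = M^t %*% D,

where the diffusion time `t` is the random-walk length. The choice that
matters is **where distances are measured**. Measuring them in plain PCA
space lets diffusion leak across distinct phenotypes as `t`, `knn`, or the
PCA dimensionality grow — over-smoothing that erases marker genes. This
package computes distances in a PCA-initialized UMAP embedding
(PCA -> UMAP -> Euclidean distances), which separates phenotypic
neighborhoods and keeps the imputation robust across parameter settings.

The package provides:

- `library_size_normalize()`, `transform_expression()`, `select_hvg()`,
  `read_expr_matrix()` / `write_expr_matrix()` (CSV/TSV/MatrixMarket);
- `embed_cells()`, `cell_distances()`, `explained_variance_components()`;
- the diffusion core: `adaptive_bandwidths()`, `adaptive_kernel()`,
  `symmetrize_affinity()`, `markov_normalize()`, `diffuse()`,
  `impute_expression()`, and the one-call wrapper `phenix_impute()`;
- diagnostics on `M^t`: `mt_to_distance()`, stress-minimizing SGD MDS
  (`mds_embed()`), HDBSCAN density audit (`density_audit()`), and
  leave-one-out kNN accuracy (`local_structure_accuracy()`);
- signed Earth Mover's Distance differential expression
  (`emd_1d()`, `emd_score_table()`) and Tukey-HSD marker over-smoothing
  evaluation (`marker_overspread_eval()`);
- a corruption/recovery benchmark (`corrupt_matrix()`,
  `recovery_metrics()`, `sweep_pca_dims()`, `sweep_params()`);
- deterministic synthetic data: `make_trajectory()` (smooth developmental
  continuum) and `make_clusters()` (phenotypes with planted markers).

## Worked example

```r
library(scphenix)

traj <- make_trajectory(n_cells = 300, n_genes = 200, seed = 1)   # smooth continuum
cc   <- corrupt_matrix(traj$expr, keep_fraction = 0.8, seed = 2)  # 20% dropout

fit <- phenix_impute(cc$corrupted, knn = 30, decay = 15, t = 5,
                     init = "pca-umap", n_pca = 100, n_umap = 30, seed = 1)

recovery_metrics(traj$truth, cc$corrupted)$pearson   # 0.788  (corrupted baseline)
recovery_metrics(traj$truth, fit$imputed)$pearson    # 0.984  (after imputation)
```

The two numbers are the Pearson correlation between the noiseless ground
truth and, respectively, the corrupted matrix and the imputed matrix:
diffusion on the PCA-UMAP manifold recovers most of the structure dropout
destroyed. The robustness claim is just as checkable:

```r
cl <- make_clusters(seed = 1)
cc <- corrupt_matrix(cl$expr, 0.8, seed = 3)
dims <- c(5, 10, 25, 50, 100)
sweep_pca_dims(cl$truth, cc$corrupted, dims, knn = 30, decay = 15, t = 5,
               init = "pca-umap")$per_dim$pearson |> var()   # 7.6e-06
sweep_pca_dims(cl$truth, cc$corrupted, dims, knn = 30, decay = 15, t = 5,
               init = "pca")$per_dim$pearson |> var()        # 1.6e-03
```

The recovery quality of the PCA-UMAP initialization barely moves as the PCA
dimensionality sweeps over an order of magnitude; plain PCA initialization
is two orders of magnitude more variable.

A command-line front end for shell pipelines lives at
`inst/cli/scphenix.R` (`preprocess`, `impute`, `visualize`, `audit`,
`dge-emd`, `bench`, `synth`).

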