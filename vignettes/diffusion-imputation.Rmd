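---
title: "Diffusion imputation on a PCA-UMAP manifold: model, parameters, and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion imputation on a PCA-UMAP manifold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scphenix)
```

## The model

Dropout in single-cell RNA-seq produces technical zeros that corrupt
gene-gene relationships and cluster geometry. Diffusion imputation treats
the cells as nodes of a weighted graph and replaces each expression profile
with a random-walk average of its neighborhood. The pipeline is a chain of
simple, inspectable linear-algebra steps:

1. **Manifold initialization.** The (normalized, transformed) matrix is
   reduced by PCA and the PCA scores are embedded by UMAP
   (`embed_cells()`). Euclidean distances are measured in the final
   embedding space. UMAP sharpens phenotype boundaries that PCA alone
   blurs; PCA first gives UMAP a globally faithful input. Distances taken
   in this space are what make the subsequent diffusion respect phenotype
   boundaries.
2. **Adaptive kernel.** `A[i, j] = exp(-(d(i, j)/sigma_i)^decay)` with
   `sigma_i` the distance from cell i to its `knn`-th nearest neighbor
   (self excluded). The bandwidth adapts to local density, so sparse and
   dense regions are treated comparably. The kernel is evaluated densely on
   all pairs; nothing is truncated.
3. **Symmetrization and normalization.** `A_sim = A + t(A)` (the sum as
   such; the factor 2 relative to averaging cancels in the next step, which
   a unit test asserts), then each row is divided by its sum, giving the
   row-stochastic Markov matrix `M`.
4. **Diffusion and imputation.** `M^t` is computed by exponentiation by
   squaring with dense multiplications; `D_imputed = M^t %*% D`. Because
   every row of `M^t` sums to one, each imputed value is a convex
   combination of observed values of the same gene — imputation can never
   leave the observed range, and a constant gene is a fixed point.

## Parameters that matter

| parameter | meaning | default | notes |
|---|---|---|---|
| `knn` | neighbor rank defining the kernel bandwidth | 30 | larger values widen the neighborhood a cell can borrow information from |
| `decay` | kernel exponent | 1 | 1 is heavy-tailed; large values (e.g. 15) approach a hard radius cut at `sigma_i` |
| `t` | diffusion time (random-walk length) | 5 | the main smoothing dial; gene variance is non-increasing in `t` |
| `n_pca` | PCA components feeding UMAP | 100 | swept in the benchmark; robustness to this choice is the method's selling point |
| `n_umap` | UMAP components | 30 | embeddings of fewer than ~3 UMAP dimensions can fail to preserve high-dimensional distances and are avoided |
| `umap_min_dist`, `umap_n_epochs`, `umap_metric` | UMAP layout settings | 0.5, 1000, euclidean | passed through to `uwot::umap()`; distances in the final space are always Euclidean |

Preprocessing exposes both `sqrt` and `log1p` transforms without forcing a
default: square root suits library-size-normalized counts whose scale
should be kept; `log1p` suits data with a wide dynamic range. Variable-gene
selection (`select_hvg()`) uses per-gene variance as the dispersion
statistic and records that choice in the output metadata.

## What the synthetic generators emulate — and what they do not

`make_trajectory()` produces cells along a latent time `s` in [0, 1] whose
genes follow smooth logistic and Gaussian-bump programs plus truncated
Gaussian noise. It emulates continuum-structured data: gradual progressive
change, no branching. The bump programs are deliberately non-monotone —
over-smoothing flattens bumps first, which makes the failure mode visible
in a recovery benchmark. `make_clusters()` produces distinct phenotypes
whose centroids sit at an exact pairwise separation (each cluster elevates
a disjoint block of program genes), with disjoint marker genes elevated
only in their own cluster.

Default conditions, chosen once as realistic for a small benchmark:
trajectory 300 cells x 200 genes with noise SD 0.5 against program
amplitudes of 2-10; clusters 3 x 50 cells x 120 genes, marker effect +3
(three noise SDs) on baselines in [0.5, 2] so marker fold change stays
above 2 on the count scale, centroid separation 6, noise SD 1. Corruption
is Bernoulli per entry at keep fraction 0.8.

What passing tests on these fixtures shows: the diffusion operator
conserves mass, respects phenotype blocks, recovers smooth structure from
uniform dropout, and is more robust to PCA dimensionality with PCA-UMAP
initialization. What it does not show: behavior under expression-dependent
dropout (real dropout is biased toward low expression; the generator's is
uniform), UMI count noise (values are real-valued Gaussian around the
programs), batch effects, or doublets. An expression-weighted corruption
mode would be a labeled extension, not the default.

## Evaluation machinery

**Corruption/recovery.** `corrupt_matrix()` zeroes entries uniformly at a
given keep fraction; `recovery_metrics()` reports Pearson, Spearman, and
R² (imputed as predictor of truth) over all entries — a masked-entries-only
mode is available via its `mask` argument. `sweep_pca_dims()` repeats the
full pipeline over a grid of dimensionalities and summarizes each metric
curve by its trapezoidal AUC normalized by the span of the dimension axis,
so AUCs are on the metric's own scale and comparable across grids (the
convention is recorded in the result's params).

**EMD differential expression.** `emd_score_table()` scores each gene in
each cluster by the first Wasserstein distance between in-cluster and
out-of-cluster expression, signed by the mean difference. The 1-D EMD is
computed exactly as the integral of |ECDF difference| over the pooled
support; for equal-sized samples this reduces to the mean absolute
difference of sorted values, which the tests use as an independent oracle.

**Marker over-smoothing.** `marker_overspread_eval()` asks, for each known
marker, in which phenotypes it is differentially expressed after
imputation: Tukey's HSD on a one-way fit (family-wise error `alpha`),
requiring the phenotype's mean to be significantly above the others and at
least `fold_change` times the mean of the rest (pseudo-count 1e-9 guards
the ratio). Diffusion's smoothing toward within-phenotype normality is what
makes the Tukey test appropriate here — on raw dropout-ridden counts it
would not be. Two aggregation rules are shipped: `"all"` (significant above
every other phenotype — the strictest reading of marker specificity, the
default) and `"majority"` (above more than half), because a marker smeared
equally into a second phenotype can never be significant against it, and
the two rules answer slightly different questions about partial smearing.
Calls are compared against the planted truth to give precision, recall, and
F1 over all marker-phenotype pairs.

**Geometry diagnostics.** `mt_to_distance()` measures Euclidean distance
between rows of `M^t` (cells with similar transition profiles are close);
`mds_embed()` projects it to 2-D/3-D; `density_audit()` runs HDBSCAN on the
distance matrix (precomputed mode, noise labeled -1, default
`min_cluster_size = 15`, always echoed in the output);
`local_structure_accuracy()` scores leave-one-out kNN label prediction.
Leave-one-out was chosen over a train/test split because it is
deterministic and split-free; ties in the majority vote are broken by the
class of the nearest tied-class neighbor.

## Numerical choices

- **SGD-MDS step schedule.** Each epoch visits every pair once in a fresh
  random order and moves the pair toward its target distance by a step
  `min(1, eta)`; `eta` decays geometrically from `eta0 = 1` to
  `eta_min = 1e-3`. Starting at 1 — placing early pairs at their exact
  target distances — is what makes small configurations converge; a timid
  start (e.g. 0.1) measurably under-converges because the total contraction
  over a finite schedule is bounded by the sum of the step sizes.
- **Stress monotonicity.** Plain pairwise SGD can fluctuate; `mds_embed`
  evaluates the normalized stress after each epoch and rolls back an epoch
  that worsened it, so the reported per-epoch trace is non-increasing by
  construction while the step schedule keeps decaying. Coincident points
  (zero embedded distance) are skipped within an epoch since their gradient
  direction is undefined.
- **Exponentiation.** `diffuse()` uses exponentiation by squaring with
  dense products rather than eigendecomposition: `M` is non-symmetric, and
  repeated multiplication is exact and cheap at the scale this package
  targets (hundreds to a few thousand cells). The eigendecomposition route
  serves as an independent oracle in the tests instead.
- **Degenerate inputs.** Zero-total cells are an error at normalization
  (filtering belongs upstream, not silently inside); a cell with `knn` or
  more exact duplicates has bandwidth zero and is an error naming the cell;
  `t = 0` returns the identity (imputation is then the identity map);
  a 1-cell matrix normalizes to `[[1]]`.
- **Problem sizes.** The test-suite and acceptance benchmarks use 300 x 200
  trajectories, 150 x 120 cluster fixtures, 10-20 replicate seeds, and a
  {5, 10, 25, 50, 100} dimension sweep — sizes at which every property
  under test is already expressed and the full suite runs in about two
  minutes.

## Known limitations

- The UMAP stage is delegated to `uwot`; bit-reproducibility of embeddings
  holds for a fixed seed within one environment but not across BLAS/uwot
  versions. Downstream quantities asserted in tests are therefore
  properties (mass conservation, ordering, accuracy thresholds), not
  hard-coded coordinates.
- The dense kernel and dense `M^t` are O(n²) in memory; this implementation
  targets desk-scale datasets, not atlas-scale ones. Landmark or truncated
  approximations are deliberately out of scope.
- `density_audit()` requires a `python` interpreter with scikit-learn on
  the PATH, since no HDBSCAN implementation is available in R here; the
  delegation is behind a single function so it can be swapped for a native
  implementation without touching callers.
- Automatic selection of `t` is not provided: the choice is exposed,
  defaulted to 5, and its effect is measurable with the over-smoothing
  diagnostics this package ships.
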