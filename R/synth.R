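#' Synthetic smooth developmental trajectory
#'
#' Generates cells ordered along a latent time s in \[0, 1\] whose genes
#' follow smooth programs of s — logistic switches and Gaussian bumps (the
#' bumps give non-monotone trends, the shape over-smoothing flattens first)
#' — plus Gaussian noise floored at zero. This emulates bulk or single-cell
#' data with continuum structure: gradual, progressive expression change
#' without branching.
#'
#' @param n_cells Number of cells (default 300).
#' @param n_genes Number of genes (default 200).
#' @param n_programs Number of distinct gene programs (default 8; half
#'   logistic, half bump, at least one of each).
#' @param noise_sd Gaussian noise standard deviation (default 0.5, about 5%
#'   of the maximal program amplitude).
#' @param seed Integer seed; output is reproducible.
#' @return List: `expr` (noisy cells x genes matrix), `pseudotime` (latent
#'   s per cell), `truth` (noiseless matrix).
#' @export
make_trajectory <- function(n_cells = 300, n_genes = 200, n_programs = 8,
                            noise_sd = 0.5, seed = 1) {
  if (n_programs > n_genes) stop("n_programs must not exceed n_genes")
  if (n_programs < 2L) stop("need at least 2 programs (one logistic, one bump)")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  with_seed(seed, {
    s <- seq(0, 1, length.out = n_cells)
    n_logistic <- ceiling(n_programs / 2)
    programs <- vector("list", n_programs)
    for (p in seq_len(n_programs)) {
      if (p <= n_logistic) {
        center <- stats::runif(1, 0.2, 0.8)
        slope <- stats::runif(1, 5, 15) * sample(c(-1, 1), 1)
        programs[[p]] <- 1 / (1 + exp(-slope * (s - center)))
      } else {
        center <- stats::runif(1, 0.15, 0.85)
        width <- stats::runif(1, 0.05, 0.2)
        programs[[p]] <- exp(-(s - center)^2 / (2 * width^2))
      }
    }
    assignment <- sample(rep_len(seq_len(n_programs), n_genes))
    amplitude <- stats::runif(n_genes, 2, 10)
    baseline <- stats::runif(n_genes, 0, 1)
    truth <- vapply(seq_len(n_genes), function(g) {
      baseline[g] + amplitude[g] * programs[[assignment[g]]]
    }, numeric(n_cells))
    dimnames(truth) <- list(sprintf("cell_%03d", seq_len(n_cells)),
                            sprintf("gene_%03d", seq_len(n_genes)))
    expr <- pmax(truth + matrix(stats::rnorm(length(truth), sd = noise_sd),
                                n_cells, n_genes), 0)
    dimnames(expr) <- dimnames(truth)
    list(expr = expr, pseudotime = s, truth = truth)
  })
}

#' Synthetic clustered population with planted marker genes
#'
#' Generates distinct cell phenotypes as Gaussian clusters whose centroids
#' sit at exactly `separation` from one another in gene space (each cluster
#' elevates its own disjoint block of program genes), with a disjoint set of
#' marker genes per cluster elevated by `marker_effect` only in that
#' cluster. The marker truth map is the ground truth for over-smoothing
#' evaluation: an imputation method that smears a marker into neighboring
#' phenotypes loses precision against it.
#'
#' @param n_clusters Number of phenotypes (default 3).
#' @param cells_per_cluster Cells per phenotype (default 50).
#' @param n_genes Number of genes (default 120).
#' @param n_markers_per_cluster Planted markers per phenotype (default 5).
#' @param marker_effect Mean elevation of a marker in its phenotype
#'   (default 3, several noise SDs).
#' @param separation Exact pairwise centroid distance in gene space
#'   (default 6).
#' @param noise_sd Gaussian noise SD (default 1).
#' @param n_program_genes Genes in each cluster's identity block
#'   (default 10).
#' @param seed Integer seed.
#' @return List: `expr` (noisy matrix), `labels` (per-cell phenotype),
#'   `markers` (named list marker gene -> its phenotype), `truth`
#'   (noiseless matrix).
#' @export
make_clusters <- function(n_clusters = 3, cells_per_cluster = 50, n_genes = 120,
                          n_markers_per_cluster = 5, marker_effect = 3,
                          separation = 6, noise_sd = 1,
                          n_program_genes = 10, seed = 1) {
  if (n_clusters < 2L) stop("need at least 2 clusters")
  needed <- n_clusters * (n_markers_per_cluster + n_program_genes)
  if (needed > n_genes) {
    stop(sprintf("n_genes (%d) too small for %d disjoint marker+program genes", n_genes, needed))
  }
  if (marker_effect <= 0 || separation <= 0) stop("marker_effect and separation must be positive")
  with_seed(seed, {
    n_cells <- n_clusters * cells_per_cluster
    labels <- rep(sprintf("cluster_%d", seq_len(n_clusters)), each = cells_per_cluster)
    gene_ids <- sprintf("gene_%03d", seq_len(n_genes))
    baseline <- stats::runif(n_genes, 0.5, 2)
    truth <- matrix(rep(baseline, each = n_cells), n_cells, n_genes,
                    dimnames = list(sprintf("cell_%03d", seq_len(n_cells)), gene_ids))

    # disjoint gene blocks: per-cluster markers first, then identity programs
    pool <- sample(n_genes)
    markers <- list()
    idx <- 1L
    for (cl in seq_len(n_clusters)) {
      mk <- pool[idx:(idx + n_markers_per_cluster - 1L)]
      idx <- idx + n_markers_per_cluster
      in_cl <- labels == sprintf("cluster_%d", cl)
      truth[in_cl, mk] <- truth[in_cl, mk] + marker_effect
      for (g in mk) markers[[gene_ids[g]]] <- sprintf("cluster_%d", cl)
    }
    # identity blocks put centroids at exactly `separation` from each other:
    # offsetting n_program_genes disjoint genes by delta gives pairwise
    # centroid distance sqrt(2 * n_program_genes * delta^2) from the blocks
    # (marker blocks add a fixed extra separation on top).
    delta <- separation / sqrt(2 * n_program_genes)
    for (cl in seq_len(n_clusters)) {
      pg <- pool[idx:(idx + n_program_genes - 1L)]
      idx <- idx + n_program_genes
      in_cl <- labels == sprintf("cluster_%d", cl)
      truth[in_cl, pg] <- truth[in_cl, pg] + delta
    }

    expr <- pmax(truth + matrix(stats::rnorm(length(truth), sd = noise_sd),
                                nrow(truth), ncol(truth)), 0)
    dimnames(expr) <- dimnames(truth)
    list(expr = expr, labels = labels, markers = markers, truth = truth)
  })
}
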