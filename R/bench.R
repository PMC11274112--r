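#' Corrupt an expression matrix with uniform random dropout
#'
#' Every entry is independently set to zero with probability
#' `1 - keep_fraction`, emulating technical dropout in which any transcript
#' has an equal chance of being missed. The Bernoulli mask is returned so
#' recovery metrics can optionally be restricted to corrupted entries.
#'
#' @param x Cells x genes matrix.
#' @param keep_fraction Probability of keeping an entry, in (0, 1\].
#' @param seed Integer seed; the mask is deterministic given the seed.
#' @return List with `corrupted` (matrix) and `mask` (logical matrix, TRUE
#'   where an entry was forced to zero).
#' @export
corrupt_matrix <- function(x, keep_fraction = 0.8, seed = 42) {
  validate_expression_matrix(x, require_names = FALSE)
  if (!is.numeric(keep_fraction) || keep_fraction <= 0 || keep_fraction > 1) {
    stop("keep_fraction must be in (0, 1]")
  }
  mask <- with_seed(seed, {
    matrix(stats::runif(length(x)) > keep_fraction, nrow(x), ncol(x))
  })
  corrupted <- x
  corrupted[mask] <- 0
  list(corrupted = corrupted, mask = mask)
}

#' Recovery metrics between an original and an imputed matrix
#'
#' Pearson and Spearman correlation and the coefficient of determination
#' (R^2, treating the imputed values as predictions of the originals),
#' computed over all matrix entries flattened, or over a subset given by
#' `mask`.
#'
#' @param original,imputed Matrices of identical shape and ordering.
#' @param mask Optional logical matrix restricting the comparison (e.g. the
#'   corrupted entries only).
#' @return Named list: `pearson`, `spearman`, `r2`.
#' @export
recovery_metrics <- function(original, imputed, mask = NULL) {
  if (!identical(dim(original), dim(imputed))) {
    stop("original and imputed must have identical dimensions")
  }
  o <- as.numeric(original)
  m <- as.numeric(imputed)
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(original))) stop("mask dimensions must match")
    o <- o[as.logical(mask)]
    m <- m[as.logical(mask)]
  }
  list(
    pearson = stats::cor(o, m, method = "pearson"),
    spearman = stats::cor(o, m, method = "spearman"),
    r2 = 1 - sum((o - m)^2) / sum((o - mean(o))^2)
  )
}

# Trapezoidal AUC over (x, y), normalized by the span of x so the result is
# on the scale of y and comparable across different grids.
.normalized_auc <- function(x, y) {
  if (length(x) == 1L) return(y)
  sum(diff(x) * (y[-1L] + y[-length(y)]) / 2) / (max(x) - min(x))
}

#' Recovery curve over a sweep of embedding dimensions
#'
#' For each number of components, runs the full pipeline
#' (embed, diffuse, impute) on the corrupted matrix and computes recovery
#' metrics against the uncorrupted truth; summarizes each metric's curve by
#' its span-normalized trapezoidal AUC, a measure of robustness to the
#' choice of dimensionality.
#'
#' @param x_true Uncorrupted reference matrix.
#' @param x_corrupt Corrupted matrix of the same shape.
#' @param dims Ascending vector of component counts; swept as `n_pca` for
#'   `"pca"` / `"pca-umap"` initializations and as `n_umap` for `"umap"`.
#' @param knn,decay,t,init,n_umap,seed Pipeline settings, see
#'   [phenix_impute()]; `n_umap` is capped at the swept input dimension so
#'   the UMAP stage never asks for more components than it is fed.
#' @param ... Further arguments to [embed_cells()].
#' @return List of class `recovery_sweep`: `per_dim` (data.frame with
#'   columns `n_dim`, `pearson`, `spearman`, `r2`), `auc` (named vector),
#'   `params`.
#' @export
sweep_pca_dims <- function(x_true, x_corrupt, dims, knn = 30, decay = 1, t = 5,
                           init = c("pca-umap", "pca", "umap"),
                           n_umap = 30, seed = 42, ...) {
  init <- match.arg(init)
  if (is.unsorted(dims, strictly = TRUE)) stop("dims must be sorted ascending without ties")
  if (max(dims) > min(dim(x_corrupt))) {
    stop("largest dim exceeds min(cells, genes) of the input")
  }
  rows <- lapply(dims, function(d) {
    fit <- if (init == "umap") {
      phenix_impute(x_corrupt, knn = knn, decay = decay, t = t, init = "umap",
                    n_umap = d, seed = seed, ...)
    } else {
      phenix_impute(x_corrupt, knn = knn, decay = decay, t = t, init = init,
                    n_pca = d, n_umap = min(n_umap, d), seed = seed, ...)
    }
    met <- recovery_metrics(x_true, fit$imputed)
    data.frame(n_dim = d, pearson = met$pearson,
               spearman = met$spearman, r2 = met$r2)
  })
  per_dim <- do.call(rbind, rows)
  auc <- vapply(c("pearson", "spearman", "r2"),
                function(mname) .normalized_auc(per_dim$n_dim, per_dim[[mname]]),
                numeric(1L))
  structure(
    list(per_dim = per_dim, auc = auc,
         params = list(knn = knn, decay = decay, t = t, init = init,
                       n_umap = n_umap, seed = seed,
                       auc_convention = "trapezoid over dims, normalized by dim span")),
    class = "recovery_sweep"
  )
}

#' @export
print.recovery_sweep <- function(x, ...) {
  cat(sprintf("<recovery_sweep> init=%s over dims {%s}\n",
              x$params$init, paste(x$per_dim$n_dim, collapse = ", ")))
  cat(sprintf("  AUC: pearson=%.4f spearman=%.4f r2=%.4f\n",
              x$auc[["pearson"]], x$auc[["spearman"]], x$auc[["r2"]]))
  invisible(x)
}

#' Local-structure accuracy over a parameter grid
#'
#' For every combination of knn, diffusion time and embedding
#' dimensionality: build the exponentiated Markov matrix, embed it in 2-D by
#' stress-minimizing SGD MDS, and score leave-one-out kNN label accuracy —
#' a grid of how well each parameter combination preserves cluster
#' structure in the diffusion geometry.
#'
#' @param x Cells x genes matrix.
#' @param labels Per-cell class labels.
#' @param knn_grid,t_grid,dim_grid Parameter grids.
#' @param init Initialization chain, as in [phenix_impute()].
#' @param decay Kernel exponent.
#' @param n_umap UMAP components for `"pca-umap"`.
#' @param classifier_k Neighbors for the leave-one-out accuracy (default 30,
#'   capped at n cells - 1).
#' @param mds_n_iter MDS epochs per grid cell.
#' @param seed Integer seed.
#' @return data.frame with columns `knn`, `t`, `n_dim`, `accuracy`.
#' @export
sweep_params <- function(x, labels, knn_grid, t_grid, dim_grid,
                         init = c("pca-umap", "pca", "umap"),
                         decay = 1, n_umap = 30, classifier_k = 30,
                         mds_n_iter = 60, seed = 42) {
  init <- match.arg(init)
  classifier_k <- min(classifier_k, nrow(x) - 1L)
  out <- list()
  for (d in dim_grid) {
    emb <- switch(init,
      "pca-umap" = embed_cells(x, n_pca = d, n_umap = n_umap, seed = seed),
      "pca"      = embed_cells(x, n_pca = d, n_umap = NULL, seed = seed),
      "umap"     = embed_cells(x, n_pca = NULL, n_umap = d, seed = seed))
    d_dist <- cell_distances(emb)
    for (knn in knn_grid) {
      sigma <- adaptive_bandwidths(d_dist, knn)
      m <- markov_normalize(symmetrize_affinity(adaptive_kernel(d_dist, sigma, decay)))
      for (t in t_grid) {
        mt <- diffuse(m, t)
        mds <- mds_embed(mt_to_distance(mt), dims = 2, seed = seed,
                         n_iter = mds_n_iter)
        acc <- local_structure_accuracy(mds, labels, k = classifier_k)
        out[[length(out) + 1L]] <- data.frame(knn = knn, t = t, n_dim = d,
                                              accuracy = acc)
      }
    }
  }
  do.call(rbind, out)
}
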