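#' @importFrom Rcpp sourceCpp
#' @useDynLib scphenix, .registration = TRUE
NULL

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Build a low-dimensional initialization space for diffusion
#'
#' Chains PCA and/or UMAP to produce the coordinates from which cell-cell
#' distances are measured. The default chain is PCA followed by UMAP: PCA
#' acts as an informative initialization that preserves global structure,
#' and UMAP sharpens local neighborhoods, so that Euclidean distances in the
#' resulting space separate distinct phenotypes. UMAP embeddings of fewer
#' than ~3 components can fail to preserve high-dimensional distances, so
#' `n_umap` defaults well above that.
#'
#' @param x Cells x genes matrix (typically normalized and transformed).
#' @param n_pca Number of principal components, or NULL to skip PCA.
#' @param n_umap Number of UMAP components, or NULL to skip UMAP.
#' @param umap_n_neighbors,umap_min_dist,umap_metric,umap_n_epochs UMAP graph
#'   and layout settings, passed through to [uwot::umap()].
#' @param seed Integer seed; the embedding is reproducible for a fixed seed.
#' @return An object of class `cell_embedding`: list with `coords`
#'   (cells x d matrix, rownames = cell ids), `method` (e.g. `"pca>umap"`),
#'   `params`, and `seed`.
#' @export
embed_cells <- function(x, n_pca = 100, n_umap = 30,
                        umap_n_neighbors = 15, umap_min_dist = 0.5,
                        umap_metric = "euclidean", umap_n_epochs = 1000,
                        seed = 42) {
  validate_expression_matrix(x, require_names = FALSE)
  if (is.null(n_pca) && is.null(n_umap)) {
    stop("at least one of n_pca, n_umap must be given")
  }
  n <- nrow(x)
  chain <- character(0)
  coords <- x

  if (!is.null(n_pca)) {
    if (n_pca < 1 || n_pca > min(dim(x))) {
      stop(sprintf("n_pca must be in [1, min(cells, genes)] = [1, %d]", min(dim(x))))
    }
    coords <- .pca_scores(coords, n_pca)
    chain <- c(chain, "pca")
  }

  if (!is.null(n_umap)) {
    if (n <= umap_n_neighbors) {
      stop(sprintf("UMAP needs more cells (%d) than n_neighbors (%d)", n, umap_n_neighbors))
    }
    coords <- with_seed(seed, uwot::umap(
      coords,
      n_components = n_umap,
      n_neighbors = umap_n_neighbors,
      min_dist = umap_min_dist,
      metric = umap_metric,
      n_epochs = umap_n_epochs,
      n_threads = 1,
      n_sgd_threads = 0,
      verbose = FALSE
    ))
    chain <- c(chain, "umap")
  }

  coords <- as.matrix(coords)
  rownames(coords) <- rownames(x)
  structure(
    list(coords = coords,
         method = paste(chain, collapse = ">"),
         params = list(n_pca = n_pca, n_umap = n_umap,
                       umap_n_neighbors = umap_n_neighbors,
                       umap_min_dist = umap_min_dist,
                       umap_metric = umap_metric,
                       umap_n_epochs = umap_n_epochs),
         seed = seed),
    class = "cell_embedding"
  )
}

# Mean-centered PCA scores (no unit-variance scaling), first n_pca components.
.pca_scores <- function(x, n_pca) {
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pca)
  p$x[, seq_len(min(n_pca, ncol(p$x))), drop = FALSE]
}

#' @export
print.cell_embedding <- function(x, ...) {
  cat(sprintf("<cell_embedding> %d cells x %d dims, method=%s, seed=%d\n",
              nrow(x$coords), ncol(x$coords), x$method, x$seed))
  invisible(x)
}

#' Number of principal components reaching a variance target
#'
#' @param x Cells x genes matrix.
#' @param target_fraction Cumulative explained-variance target in (0, 1\].
#' @return Smallest number of components whose cumulative explained-variance
#'   ratio reaches `target_fraction`.
#' @export
explained_variance_components <- function(x, target_fraction) {
  validate_expression_matrix(x, require_names = FALSE)
  if (!is.numeric(target_fraction) || target_fraction <= 0 || target_fraction > 1) {
    stop("target_fraction must be in (0, 1]")
  }
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  total <- sum(ev)
  if (total <= 0) stop("degenerate matrix: zero total variance")
  cum <- cumsum(ev) / total
  as.integer(which(cum >= target_fraction - 1e-12)[1L])
}

#' Pairwise Euclidean cell-cell distance matrix
#'
#' @param embedding A `cell_embedding` or a cells x d coordinate matrix.
#' @return Symmetric n x n distance matrix with zero diagonal.
#' @export
cell_distances <- function(embedding) {
  coords <- if (inherits(embedding, "cell_embedding")) embedding$coords else as.matrix(embedding)
  if (anyNA(coords) || any(!is.finite(coords))) stop("coordinates must be finite")
  d <- as.matrix(stats::dist(coords, method = "euclidean"))
  dimnames(d) <- list(rownames(coords), rownames(coords))
  d
}
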