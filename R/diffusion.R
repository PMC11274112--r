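#' Per-cell adaptive kernel bandwidths
#'
#' The bandwidth of cell i is the distance to its knn-th nearest neighbor
#' (self excluded), so kernel width tracks local density: tight in dense
#' regions, wide in sparse ones.
#'
#' @param d_dist Symmetric cell-cell distance matrix.
#' @param knn Neighbor rank defining the bandwidth; `1 <= knn < n cells`.
#' @return Vector of positive bandwidths, one per cell.
#' @export
adaptive_bandwidths <- function(d_dist, knn) {
  .validate_distance_matrix(d_dist)
  n <- nrow(d_dist)
  if (knn < 1 || knn >= n) stop(sprintf("knn must satisfy 1 <= knn < n cells (%d)", n))
  sigma <- vapply(seq_len(n), function(i) {
    d <- sort(d_dist[i, -i])
    d[knn]
  }, numeric(1L))
  if (any(sigma <= 0)) {
    bad <- which(sigma <= 0)[1L]
    stop(sprintf(paste0("cell %d has %d or more exact duplicates (bandwidth 0); ",
                        "deduplicate or jitter the input"), bad, knn))
  }
  sigma
}

#' Adaptive Gaussian kernel affinity matrix
#'
#' `A[i, j] = exp(-(d(i, j) / sigma_i)^decay)`. Each row uses its own
#' bandwidth, so the matrix is not symmetric; the diagonal is 1. The decay
#' exponent controls how sharply affinity falls off with normalized
#' distance: 1 gives a heavy-tailed kernel, large values approach a hard
#' knn-radius cutoff.
#'
#' @param d_dist Symmetric distance matrix.
#' @param sigma Bandwidth vector from [adaptive_bandwidths()].
#' @param decay Positive kernel exponent.
#' @return Non-symmetric affinity matrix with entries in (0, 1].
#' @export
adaptive_kernel <- function(d_dist, sigma, decay = 1) {
  .validate_distance_matrix(d_dist)
  if (length(sigma) != nrow(d_dist)) stop("sigma length must equal number of cells")
  if (any(sigma <= 0)) stop("all bandwidths must be positive")
  if (!is.numeric(decay) || length(decay) != 1L || decay <= 0) {
    stop("decay must be a single positive number")
  }
  a <- exp(-(d_dist / sigma)^decay)  # sigma recycles down columns = per-row bandwidth
  diag(a) <- 1
  a
}

#' Symmetrize an affinity matrix by adding its transpose
#'
#' Returns `A + t(A)`. The global factor of 2 this introduces relative to
#' averaging is irrelevant after row normalization.
#'
#' @param a Square affinity matrix.
#' @return Symmetric affinity matrix.
#' @export
symmetrize_affinity <- function(a) {
  if (!is.matrix(a) || nrow(a) != ncol(a)) stop("affinity matrix must be square")
  a + t(a)
}

#' Row-normalize a symmetric affinity matrix into a Markov matrix
#'
#' Divides each row by its sum, producing a row-stochastic transition matrix
#' whose row i is the probability distribution of a one-step random walk
#' from cell i.
#'
#' @param a_sim Symmetric affinity matrix with positive row sums.
#' @return Row-stochastic Markov matrix.
#' @export
markov_normalize <- function(a_sim) {
  if (!is.matrix(a_sim) || nrow(a_sim) != ncol(a_sim)) stop("affinity matrix must be square")
  rs <- rowSums(a_sim)
  if (any(rs <= 0)) stop("zero row sum in affinity matrix; cannot normalize")
  a_sim / rs
}

#' Diffuse: raise the Markov matrix to an integer power
#'
#' `M^t[i, j]` is the probability that a t-step random walk from cell i ends
#' at cell j. Exponentiation is by squaring with dense multiplications,
#' which preserves row-stochasticity to numerical precision; `t = 0` gives
#' the identity.
#'
#' @param m Row-stochastic Markov matrix.
#' @param t Non-negative integer diffusion time.
#' @return `M^t` with attribute `t_applied`.
#' @export
diffuse <- function(m, t) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("Markov matrix must be square")
  if (!is.numeric(t) || length(t) != 1L || t < 0 || t != round(t)) {
    stop("t must be a single non-negative integer")
  }
  t <- as.integer(t)
  n <- nrow(m)
  result <- diag(n)
  dimnames(result) <- dimnames(m)
  base <- m
  k <- t
  while (k > 0L) {
    if (k %% 2L == 1L) result <- result %*% base
    k <- k %/% 2L
    if (k > 0L) base <- base %*% base
  }
  attr(result, "t_applied") <- t
  result
}

#' Impute expression by diffusion
#'
#' `D_imputed = M^t %*% D`: each imputed cell profile is a convex
#' combination of observed profiles weighted by t-step random-walk
#' probabilities, so every imputed value lies between the observed minimum
#' and maximum of its gene.
#'
#' @param mt Exponentiated Markov matrix (cells x cells).
#' @param d Cells x genes expression matrix in the same cell order.
#' @return Imputed cells x genes matrix.
#' @export
impute_expression <- function(mt, d) {
  validate_expression_matrix(d, require_names = FALSE)
  if (!is.matrix(mt) || nrow(mt) != ncol(mt)) stop("Markov matrix must be square")
  if (nrow(mt) != nrow(d)) {
    stop(sprintf("Markov matrix side (%d) must equal number of cells (%d)", nrow(mt), nrow(d)))
  }
  out <- mt %*% d
  dimnames(out) <- dimnames(d)
  out
}

#' Full diffusion-imputation pipeline
#'
#' Convenience wrapper chaining manifold initialization, adaptive-kernel
#' Markov matrix construction, t-step diffusion and imputation.
#'
#' @param x Cells x genes matrix (already normalized/transformed as desired).
#' @param knn Neighbor rank for the adaptive bandwidth (default 30).
#' @param decay Kernel exponent (default 1).
#' @param t Diffusion time (default 5).
#' @param init Initialization chain: `"pca-umap"` (default), `"pca"`, or
#'   `"umap"`.
#' @param n_pca,n_umap Dimensions for the PCA / UMAP stages.
#' @param seed Integer seed for the stochastic embedding stages.
#' @param ... Further arguments to [embed_cells()] (UMAP settings).
#' @return List of class `scphenix_fit`: `imputed`, `mt`, `markov`,
#'   `embedding`, `params`.
#' @export
phenix_impute <- function(x, knn = 30, decay = 1, t = 5,
                          init = c("pca-umap", "pca", "umap"),
                          n_pca = 100, n_umap = 30, seed = 42, ...) {
  init <- match.arg(init)
  emb <- switch(init,
    "pca-umap" = embed_cells(x, n_pca = n_pca, n_umap = n_umap, seed = seed, ...),
    "pca"      = embed_cells(x, n_pca = n_pca, n_umap = NULL, seed = seed, ...),
    "umap"     = embed_cells(x, n_pca = NULL, n_umap = n_umap, seed = seed, ...)
  )
  d_dist <- cell_distances(emb)
  sigma <- adaptive_bandwidths(d_dist, knn)
  m <- markov_normalize(symmetrize_affinity(adaptive_kernel(d_dist, sigma, decay)))
  mt <- diffuse(m, t)
  structure(
    list(imputed = impute_expression(mt, x),
         mt = mt,
         markov = m,
         embedding = emb,
         params = list(knn = knn, decay = decay, t = t, init = init,
                       n_pca = n_pca, n_umap = n_umap, seed = seed)),
    class = "scphenix_fit"
  )
}

#' @export
print.scphenix_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("<scphenix_fit> %d cells x %d genes | init=%s knn=%d decay=%g t=%d\n",
              nrow(x$imputed), ncol(x$imputed), p$init, p$knn, p$decay, p$t))
  invisible(x)
}

.validate_distance_matrix <- function(d, tol = 1e-9) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (any(d < 0)) stop("distance matrix has negative entries")
  if (max(abs(d - t(d))) > tol) stop("distance matrix is not symmetric")
  if (any(abs(diag(d)) > tol)) stop("distance matrix diagonal must be zero")
  invisible(d)
}
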