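#' Distance matrix between rows of an exponentiated Markov matrix
#'
#' Cells with similar t-step transition profiles (rows of `M^t`) are close;
#' this is the geometry the diffusion process actually imputes over, so
#' embedding it reveals which cells share information.
#'
#' @param mt Exponentiated Markov matrix.
#' @return Symmetric Euclidean distance matrix over the rows of `mt`.
#' @export
mt_to_distance <- function(mt) {
  if (!is.matrix(mt) || nrow(mt) != ncol(mt)) stop("Markov matrix must be square")
  as.matrix(stats::dist(mt, method = "euclidean"))
}

#' Metric MDS by pairwise stochastic gradient descent
#'
#' Embeds a distance matrix in 2 or 3 dimensions by minimizing metric-MDS
#' stress with pairwise SGD: every epoch visits each pair of points once in
#' random order and moves the pair toward its target distance, with a step
#' size decaying geometrically from `eta0` to `eta_min` across epochs
#' (`eta0 = 1` places each early pair at its exact target distance, the
#' constraint-satisfaction start of SGD stress minimization). The
#' reported stress is the normalized stress
#' `sqrt(sum (|xi - xj| - d_ij)^2 / sum d_ij^2)`; an epoch that worsens it is
#' rolled back, so the per-epoch trace is non-increasing.
#'
#' @param d Symmetric distance matrix.
#' @param dims Embedding dimensionality, 2 or 3.
#' @param seed Integer seed (initial configuration and pair order).
#' @param n_iter Number of epochs.
#' @param eta0,eta_min Initial and final step sizes of the geometric decay.
#' @return Object of class `mds_embedding`: `coords`, `stress` (final
#'   normalized stress), `stress_trace`, `seed`.
#' @export
mds_embed <- function(d, dims = 2, seed = 42, n_iter = 100,
                      eta0 = 1, eta_min = 1e-3) {
  .validate_distance_matrix(d)
  if (!dims %in% c(2, 3)) stop("dims must be 2 or 3")
  n <- nrow(d)
  if (n < dims + 1) stop(sprintf("need at least %d points for a %d-D embedding", dims + 1, dims))
  if (n_iter < 1) stop("n_iter must be a positive integer")
  etas <- eta0 * (eta_min / eta0)^(seq(0, 1, length.out = n_iter))
  res <- with_seed(seed, {
    scale0 <- max(d)
    init <- matrix(stats::rnorm(n * dims, sd = scale0 / 4), n, dims)
    sgd_mds_cpp(d, init, etas)
  })
  coords <- res$coords
  rownames(coords) <- rownames(d)
  structure(
    list(coords = coords, stress = res$stress,
         stress_trace = as.numeric(res$stress_trace), seed = seed),
    class = "mds_embedding"
  )
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("<mds_embedding> %d points x %d dims, stress=%.4g\n",
              nrow(x$coords), ncol(x$coords), x$stress))
  invisible(x)
}

#' Density cluster audit of a distance matrix
#'
#' Runs HDBSCAN in precomputed-distance mode to identify dense clusters
#' (noise labeled -1). Clustering is delegated to scikit-learn's HDBSCAN via
#' the `python` interpreter on the PATH; the matrix is exchanged through
#' temporary CSV files.
#'
#' @param d Symmetric distance matrix.
#' @param min_cluster_size Minimum cluster size (>= 2); always reported back
#'   in the result.
#' @return List of class `density_audit`: `labels` (integer, -1 = noise),
#'   `n_clusters`, `min_cluster_size`.
#' @export
density_audit <- function(d, min_cluster_size = 15) {
  .validate_distance_matrix(d)
  if (min_cluster_size < 2) stop("min_cluster_size must be at least 2")
  python <- Sys.which("python")
  if (!nzchar(python)) python <- Sys.which("python3")
  if (!nzchar(python)) {
    stop("density_audit requires a 'python' interpreter with scikit-learn on the PATH")
  }
  in_csv <- tempfile(fileext = ".csv")
  out_txt <- tempfile(fileext = ".txt")
  on.exit(unlink(c(in_csv, out_txt)))
  utils::write.table(d, in_csv, sep = ",", row.names = FALSE, col.names = FALSE)
  script <- paste(
    "import sys, numpy as np",
    "from sklearn.cluster import HDBSCAN",
    "D = np.loadtxt(sys.argv[1], delimiter=',', ndmin=2)",
    "m = HDBSCAN(min_cluster_size=int(sys.argv[2]), metric='precomputed')",
    "np.savetxt(sys.argv[3], m.fit_predict(D), fmt='%d')",
    sep = "; ")
  status <- suppressWarnings(
    system2(python, c("-c", shQuote(script), shQuote(in_csv),
                      min_cluster_size, shQuote(out_txt)),
            stdout = TRUE, stderr = TRUE))
  if (!file.exists(out_txt)) {
    stop("HDBSCAN run failed: ", paste(status, collapse = "\n"))
  }
  labels <- as.integer(readLines(out_txt))
  structure(
    list(labels = labels,
         n_clusters = length(unique(labels[labels >= 0L])),
         min_cluster_size = min_cluster_size),
    class = "density_audit"
  )
}

#' Leave-one-out kNN classification accuracy in an embedding
#'
#' Measures local-structure preservation: each cell is predicted from its k
#' nearest other cells by majority vote (ties broken by the class of the
#' nearest neighbor among the tied classes), and the fraction of correct
#' predictions is returned.
#'
#' @param embedding An `mds_embedding`, `cell_embedding`, or coordinate
#'   matrix.
#' @param labels Per-cell class labels.
#' @param k Number of neighbors; `k < n cells`.
#' @return Accuracy in \[0, 1\].
#' @export
local_structure_accuracy <- function(embedding, labels, k = 30) {
  coords <- if (inherits(embedding, c("mds_embedding", "cell_embedding"))) {
    embedding$coords
  } else {
    as.matrix(embedding)
  }
  n <- nrow(coords)
  if (length(labels) != n) stop("labels length must equal number of cells")
  if (k >= n) stop(sprintf("k (%d) must be smaller than the number of cells (%d)", k, n))
  labels <- as.character(labels)
  nn <- FNN::get.knn(coords, k = k)
  correct <- vapply(seq_len(n), function(i) {
    nbr <- nn$nn.index[i, ]
    votes <- table(labels[nbr])
    top <- names(votes)[votes == max(votes)]
    pred <- if (length(top) == 1L) {
      top
    } else {
      # tie: class of the nearest neighbor among the tied classes
      labels[nbr][labels[nbr] %in% top][1L]
    }
    pred == labels[i]
  }, logical(1L))
  mean(correct)
}
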