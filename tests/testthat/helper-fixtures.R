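# Shared fixture builders; all deterministic under the seed they take.

random_expr <- function(n_cells, n_genes, seed = 1) {
  set.seed(seed)
  expression_matrix(matrix(stats::rexp(n_cells * n_genes), n_cells, n_genes))
}

# Random point cloud -> valid distance matrix
random_distances <- function(n, d = 3, seed = 1) {
  set.seed(seed)
  cell_distances(matrix(stats::rnorm(n * d), n, d))
}

# Random row-stochastic Markov matrix (strictly positive, generically
# diagonalizable)
random_markov <- function(n, seed = 1) {
  set.seed(seed)
  a <- matrix(stats::runif(n * n, min = 0.01), n, n)
  a / rowSums(a)
}

# Markov matrix built through the package's own kernel pipeline
kernel_markov <- function(coords, knn = 5, decay = 2) {
  d <- cell_distances(coords)
  markov_normalize(symmetrize_affinity(
    adaptive_kernel(d, adaptive_bandwidths(d, knn), decay)))
}

expect_row_stochastic <- function(m, tol = 1e-9) {
  expect_lt(max(abs(rowSums(m) - 1)), tol)
  expect_true(all(m >= -tol & m <= 1 + tol))
}
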