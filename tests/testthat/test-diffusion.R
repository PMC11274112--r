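test_that("adaptive bandwidth is the distance to the knn-th neighbor, self excluded", {
  d <- cell_distances(matrix(c(0, 1, 2, 4), 4, 1))
  expect_equal(adaptive_bandwidths(d, 2)[1], 2)          # neighbors of 0: 1, 2, 4
  expect_equal(adaptive_bandwidths(d, 3), c(4, 3, 2, 4)) # knn = n-1: max distance

  # equilateral triangle: all bandwidths equal by symmetry
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_equal(adaptive_bandwidths(cell_distances(tri), 2), rep(1, 3))

  expect_error(adaptive_bandwidths(d, 4), "knn")
  dup <- cell_distances(rbind(c(0, 0), c(0, 0), c(5, 5)))
  expect_error(adaptive_bandwidths(dup, 1), "duplicates")
})

test_that("adaptive kernel reproduces its closed forms and uses per-row bandwidths", {
  d <- cell_distances(matrix(c(0, 1, 3), 3, 1))
  sigma <- adaptive_bandwidths(d, 1)  # (1, 1, 2)
  expect_equal(sigma, c(1, 1, 2))
  for (decay in c(1, 2, 15)) {
    a <- adaptive_kernel(d, sigma, decay)
    expect_equal(diag(a), rep(1, 3))               # d = 0 -> e^0 = 1
    expect_equal(a[1, 2], exp(-1))                 # d = sigma_i -> e^-1
  }
  a2 <- adaptive_kernel(d, sigma, 2)
  expect_equal(a2[2, 3], exp(-4))                  # d = 2 sigma_i, decay 2 -> e^-4
  # asymmetric: row 3 has the wider bandwidth
  expect_gt(a2[3, 2], a2[2, 3])
  expect_error(adaptive_kernel(d, sigma, 0), "decay")
})

test_that("symmetrization adds the transpose and normalization is insensitive to the factor", {
  a <- rbind(c(1, 0), c(0.5, 1))
  expect_equal(symmetrize_affinity(a), rbind(c(2, 0.5), c(0.5, 2)))
  s <- symmetrize_affinity(a)
  expect_identical(s, t(s))
  sym <- rbind(c(1, 0.3), c(0.3, 1))
  expect_equal(symmetrize_affinity(sym), 2 * sym)
  # sum vs mean symmetrization yield the same Markov matrix
  expect_equal(markov_normalize(s), markov_normalize(s / 2), tolerance = 1e-15)
})

test_that("Markov normalization produces row-stochastic matrices", {
  expect_equal(markov_normalize(rbind(c(2, 2), c(2, 2))), matrix(0.5, 2, 2))
  expect_equal(markov_normalize(matrix(3, 1, 1)), matrix(1, 1, 1))
  set.seed(31)
  a <- symmetrize_affinity(matrix(runif(25, 0.1), 5, 5))
  expect_lt(max(abs(rowSums(markov_normalize(a)) - 1)), 1e-12)
  expect_error(markov_normalize(matrix(0, 2, 2)), "zero row sum")
})

test_that("diffusion powers match hand computation and boundary cases", {
  m <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  expect_equal(unname(diffuse(m, 0)), diag(2), ignore_attr = TRUE)
  expect_equal(diffuse(m, 1), m, ignore_attr = TRUE)
  expect_equal(diffuse(m, 2), rbind(c(0.83, 0.17), c(0.34, 0.66)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(attr(diffuse(m, 5), "t_applied"), 5L)
  expect_error(diffuse(m, -1), "non-negative")
  expect_error(diffuse(m, 1.5), "integer")
})

test_that("repeated-multiplication power equals the eigendecomposition oracle", {
  for (s in 1:10) {
    m <- random_markov(20, seed = s)
    e <- eigen(m)
    for (t in c(2, 7)) {
      oracle <- Re(e$vectors %*% diag(e$values^t) %*% solve(e$vectors))
      expect_lt(max(abs(diffuse(m, t) - oracle)), 1e-6)
    }
  }
})

test_that("imputation is a convex combination bounded by observed gene extremes", {
  x <- random_expr(30, 10, seed = 32)
  m <- kernel_markov(x, knn = 5, decay = 2)
  expect_equal(impute_expression(diag(30), x), x)                  # identity Mt
  const <- expression_matrix(matrix(7, 30, 2))
  expect_equal(unname(impute_expression(diffuse(m, 4), const)),
               matrix(7, 30, 2), tolerance = 1e-9)                 # constant gene fixed
  imp <- impute_expression(diffuse(m, 3), x)
  expect_true(all(imp >= rep(apply(x, 2, min), each = 30) - 1e-9))
  expect_true(all(imp <= rep(apply(x, 2, max), each = 30) + 1e-9))

  m2 <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(unname(impute_expression(m2, expression_matrix(matrix(c(0, 10), 2, 1)))),
               matrix(5, 2, 1))
  expect_error(impute_expression(diag(3), x), "must equal")
})

test_that("gene variance of imputed data is non-increasing in diffusion time", {
  for (s in 1:3) {
    cl <- make_clusters(seed = s, n_clusters = 2, cells_per_cluster = 30, n_genes = 50)
    m <- kernel_markov(cl$expr, knn = 5, decay = 2)
    v <- vapply(c(1, 2, 4, 8, 16), function(t) {
      mean(apply(impute_expression(diffuse(m, t), cl$expr), 2, var))
    }, numeric(1))
    expect_false(is.unsorted(rev(v)))
  }
})

test_that("full pipeline wrapper reproduces its stages and is seed-stable", {
  cl <- make_clusters(n_clusters = 2, cells_per_cluster = 25, n_genes = 40, seed = 33)
  fit <- phenix_impute(cl$expr, knn = 5, decay = 2, t = 3, init = "pca",
                       n_pca = 10, seed = 5)
  d <- cell_distances(embed_cells(cl$expr, n_pca = 10, n_umap = NULL, seed = 5))
  m <- markov_normalize(symmetrize_affinity(
    adaptive_kernel(d, adaptive_bandwidths(d, 5), 2)))
  expect_equal(fit$imputed, impute_expression(diffuse(m, 3), cl$expr), tolerance = 1e-12)
  fit2 <- phenix_impute(cl$expr, knn = 5, decay = 2, t = 3, init = "pca",
                        n_pca = 10, seed = 5)
  expect_identical(fit$imputed, fit2$imputed)
})
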