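test_that("one-dimensional EMD matches closed forms and the sorted-sample oracle", {
  expect_equal(emd_1d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(emd_1d(0, 1), 1)
  expect_equal(emd_1d(c(0, 0), c(0, 2)), 1)  # sorted-difference oracle (0 + 2) / 2
  expect_error(emd_1d(numeric(0), 1), "non-empty")

  # equal-sized samples: mean absolute difference of sorted values
  set.seed(51)
  for (i in 1:50) {
    n <- sample(2:30, 1)
    u <- rnorm(n); v <- rnorm(n, mean = runif(1, -2, 2))
    expect_equal(emd_1d(u, v), mean(abs(sort(u) - sort(v))), tolerance = 1e-12)
  }
})

test_that("EMD is a metric with translation and positive-scale equivariance", {
  set.seed(52)
  for (i in 1:20) {
    u <- rexp(7); v <- rexp(5); w <- rexp(9)
    duv <- emd_1d(u, v)
    expect_equal(duv, emd_1d(v, u), tolerance = 1e-12)               # symmetry
    expect_lte(duv, emd_1d(u, w) + emd_1d(w, v) + 1e-12)             # triangle
    expect_equal(emd_1d(u + 3, v + 3), duv, tolerance = 1e-12)       # translation
    expect_equal(emd_1d(2.5 * u, 2.5 * v), 2.5 * duv, tolerance = 1e-12)  # scale
  }
})

test_that("signed EMD table matches hand ECDF computation on a 3-cluster toy", {
  # 6 cells, 2 per cluster; gene 1 is 10 only in cluster a
  x <- expression_matrix(cbind(g1 = c(10, 10, 0, 0, 0, 0),
                               g2 = rep(4, 6)))
  labs <- rep(c("a", "b", "c"), each = 2)
  tab <- emd_score_table(x, labs)
  expect_equal(tab["g1", "a"], 10)   # ECDFs differ by 1 over [0, 10)
  # rest of cluster b = {10, 10, 0, 0}: ECDF gap 0.5 over [0, 10) -> magnitude 5
  expect_equal(tab["g1", "b"], -5)
  expect_equal(tab["g1", "c"], -5)
  expect_equal(unname(tab["g2", ]), c(0, 0, 0))  # constant gene scores 0 everywhere

  # permutation invariance
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(emd_score_table(x[perm, ], labs[perm]), tab)

  expect_error(emd_score_table(x, rep("a", 6)), "2 clusters")
})

test_that("EMD score signs agree exactly with mean differences", {
  cl <- make_clusters(seed = 53, n_clusters = 3, cells_per_cluster = 20, n_genes = 40,
                      n_markers_per_cluster = 2, n_program_genes = 4)
  tab <- emd_score_table(cl$expr, cl$labels)
  for (c in colnames(tab)) {
    in_cl <- cl$labels == c
    md <- colMeans(cl$expr[in_cl, , drop = FALSE]) -
      colMeans(cl$expr[!in_cl, , drop = FALSE])
    expect_identical(sign(tab[, c]), sign(md))
  }
})

test_that("marker evaluation scores planted markers perfectly and detects uniform genes", {
  cl <- make_clusters(seed = 54)
  ev <- marker_overspread_eval(cl$expr, cl$labels, cl$markers)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$f1, 1)

  # a uniformly expressed gene yields no positive calls -> zero recall
  flat <- cl$expr
  flat[, names(cl$markers)[1]] <- rnorm(nrow(flat), mean = 5, sd = 0.1)
  ev2 <- marker_overspread_eval(flat, cl$labels,
                                cl$markers[1])
  expect_equal(unname(ev2$confusion[c("tp", "fp")]), c(0L, 0L))
  expect_equal(ev2$recall, 0)
  expect_equal(ev2$precision, 0)

  expect_error(marker_overspread_eval(cl$expr, cl$labels, list(nope = "cluster_1")),
               "absent")
  expect_error(marker_overspread_eval(cl$expr, rep("one", nrow(cl$expr)), cl$markers),
               "2 phenotypes")
})

test_that("a marker smeared into one extra phenotype halves precision under the majority rule", {
  # 4 phenotypes x 30 cells; marker truly specific to A but elevated in A and B
  set.seed(55)
  labs <- rep(c("A", "B", "C", "D"), each = 30)
  x <- expression_matrix(cbind(mk = pmax(rnorm(120, 1, 0.2) +
                                           4 * (labs %in% c("A", "B")), 0)))
  ev <- marker_overspread_eval(x, labs, list(mk = "A"), rule = "majority")
  # hand confusion matrix: calls {A, B}, truth {A} -> tp 1, fp 1, fn 0
  expect_equal(ev$precision, 0.5)
  expect_equal(ev$recall, 1)
  expect_equal(ev$f1, 2 / 3)
})

test_that("diffusion homogenizes phenotype means with increasing t", {
  cl <- make_clusters(seed = 56)
  m <- kernel_markov(cl$expr, knn = 30, decay = 1)
  between <- vapply(c(1, 3, 6, 12), function(t) {
    imp <- impute_expression(diffuse(m, t), cl$expr)
    mean(apply(imp, 2, function(g) var(tapply(g, cl$labels, mean))))
  }, numeric(1))
  expect_false(is.unsorted(rev(between)))
})
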