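test_that("row permutation is reproducible and moment-preserving", {
  vs <- random_views(8, 5, 4, seed = 1)
  a <- permute_views(vs$X1, vs$X2, seed = 9)
  b <- permute_views(vs$X1, vs$X2, seed = 9)
  expect_identical(a$X1$data, b$X1$data)
  expect_identical(a$perm2, b$perm2)
  expect_false(identical(a$perm1, a$perm2))  # independent streams

  expect_equal(colMeans(a$X1$data), colMeans(vs$X1$data), tolerance = 1e-12)
  expect_equal(apply(a$X2$data, 2, sd), apply(vs$X2$data, 2, sd),
               tolerance = 1e-12)
})

test_that("permutations are uniform over the symmetric group", {
  n <- 5
  X <- matrix(rnorm(n * 2), n, 2)
  v1 <- standardize_columns(X)
  v2 <- standardize_columns(X + rnorm(n * 2))
  key <- function(p) paste(p, collapse = "")
  counts <- table(vapply(1:10000, function(j) {
    key(permute_views(v1, v2, seed = j)$perm1)
  }, character(1)))
  expect_equal(length(counts), 120L)  # all 5! permutations occur
  chi <- sum((counts - 10000 / 120)^2 / (10000 / 120))
  # 3-sd band on the chi-square statistic with 119 df
  expect_lt(chi, 119 + 3 * sqrt(2 * 119))
})

test_that("the Fisher transform clamps and rejects out-of-range input", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493061, tolerance = 1e-6)
  expect_true(is.finite(fisher_z(1)))
  expect_true(is.finite(fisher_z(-1)))
  expect_equal(fisher_z(1), -fisher_z(-1))
  expect_error(fisher_z(1.2), "\\[-1, 1\\]")
})

test_that("the permutation z-statistic follows its definition", {
  # null whose Fisher-transformed values have mean 0.5 and sd 0.2 exactly
  q_null <- tanh(c(0.3, 0.5, 0.7))
  expect_equal(z_statistic(0.9, q_null), (atanh(0.9) - 0.5) / 0.2,
               tolerance = 1e-10)
  expect_equal(z_statistic(q_null[2], rep(q_null, 2)), 0, tolerance = 1e-10)

  # strictly increasing in the observed correlation for a fixed null
  zs <- vapply(seq(-0.9, 0.9, by = 0.1), z_statistic, numeric(1),
               q_null = q_null)
  expect_true(all(diff(zs) > 0))

  expect_warning(z0 <- z_statistic(0.9, c(0.5, 0.5, 0.5)), "zero spread")
  expect_equal(z0, .Machine$double.xmax)
  expect_error(z_statistic(0.5, 0.4), "at least 2")
})

test_that("null distributions are reproducible and in range", {
  nv <- generate_null_views(30, 50, 50, seed = 2)
  q1 <- scca_null_distribution(nv$X1, nv$X2, 0.5, 0.5, k = 30, seed = 5)
  q2 <- scca_null_distribution(nv$X1, nv$X2, 0.5, 0.5, k = 30, seed = 5)
  expect_identical(as.numeric(q1), as.numeric(q2))
  expect_true(all(q1 >= -1 & q1 <= 1))
  q3 <- scca_null_distribution(nv$X1, nv$X2, 0.5, 0.5, k = 30, seed = 6)
  expect_false(identical(as.numeric(q1), as.numeric(q3)))
})

test_that("null quantiles are stable across disjoint permutation streams", {
  nv <- generate_null_views(20, 15, 15, seed = 3)
  qa <- scca_null_distribution(nv$X1, nv$X2, 0.6, 0.6, k = 1000, seed = 11)
  qb <- scca_null_distribution(nv$X1, nv$X2, 0.6, 0.6, k = 1000, seed = 12)
  ks <- suppressWarnings(stats::ks.test(as.numeric(qa), as.numeric(qb)))
  expect_gt(ks$p.value, 0.01)
})

test_that("grid search is reproducible and respects degenerate grids", {
  sim <- generate_paired_views(n = 25, p1 = 30, p2 = 30, s1 = 4, s2 = 4,
                               seed = 8)
  sel1 <- scca_select(sim$X1, sim$X2, grid1 = c(0.4, 0.8),
                      grid2 = c(0.4, 0.8), k = 15, seed = 3)
  sel2 <- scca_select(sim$X1, sim$X2, grid1 = c(0.4, 0.8),
                      grid2 = c(0.4, 0.8), k = 15, seed = 3)
  expect_identical(sel1$z, sel2$z)       # bit-stable z matrix
  expect_identical(sel1$chosen, sel2$chosen)
  expect_equal(dim(sel1$z), c(2L, 2L))
  expect_true(all(is.finite(sel1$z)))
  expect_equal(nrow(sel1$table), 4L)

  only <- scca_select(sim$X1, sim$X2, grid1 = 0.5, grid2 = 0.7, k = 10,
                      seed = 1)
  expect_equal(only$chosen, c(c1 = 0.5, c2 = 0.7))
  expect_equal(only$fit$c1, 0.5)
  expect_error(scca_select(sim$X1, sim$X2, grid1 = numeric(0),
                           grid2 = 0.5, k = 10), "non-empty")
  expect_error(scca_select(sim$X1, sim$X2, grid1 = 1.5, grid2 = 0.5, k = 10),
               "\\(0, 1\\]")
})
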