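test_that("identical views give canonical correlation 1", {
  set.seed(3)
  X <- matrix(rnorm(20 * 5), 20, 5)
  comp <- scca_rank1(X, X, c1 = 1, c2 = 1, nonnegative = FALSE,
                     tol = 1e-9, max_iter = 500)
  expect_equal(comp$q, 1, tolerance = 1e-6)
})

test_that("with inactive L1 constraints the fit is the leading singular triple", {
  vs <- random_views(50, 4, 4, seed = 11)
  comp <- scca_rank1(vs$X1, vs$X2, c1 = 1, c2 = 1, nonnegative = FALSE,
                     tol = 1e-10, max_iter = 2000, power_iter = 50)
  sv <- svd(crossprod(vs$X1$data, vs$X2$data))
  expect_equal(abs(comp$u), abs(sv$u[, 1]), tolerance = 1e-5)
  expect_equal(abs(comp$v), abs(sv$v[, 1]), tolerance = 1e-5)
  expect_equal(abs(comp$q_raw), sv$d[1], tolerance = 1e-5)
})

test_that("every fit satisfies the L2/L1/nonnegativity constraints and ascends", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(15:40, 1)
    p1 <- sample(5:40, 1)
    p2 <- sample(5:40, 1)
    c1 <- runif(1, 0.3, 1)
    c2 <- runif(1, 0.3, 1)
    nonneg <- seed %% 2 == 0
    vs <- random_views(n, p1, p2, seed = 100 + seed)
    comp <- suppressWarnings(scca_rank1(vs$X1, vs$X2, c1 = c1, c2 = c2,
                                        nonnegative = nonneg))
    p1r <- ncol(vs$X1$data)
    p2r <- ncol(vs$X2$data)
    expect_lte(sqrt(sum(comp$u^2)), 1 + 1e-8)
    expect_lte(sqrt(sum(comp$v^2)), 1 + 1e-8)
    if (any(comp$u != 0)) expect_equal(sqrt(sum(comp$u^2)), 1, tolerance = 1e-6)
    if (any(comp$v != 0)) expect_equal(sqrt(sum(comp$v^2)), 1, tolerance = 1e-6)
    expect_lte(sum(abs(comp$u)), c1 * sqrt(p1r) + 1e-6)
    expect_lte(sum(abs(comp$v)), c2 * sqrt(p2r) + 1e-6)
    if (nonneg) {
      expect_true(all(comp$u >= 0))
      expect_true(all(comp$v >= 0))
    }
    expect_gte(comp$q, -1)
    expect_lte(comp$q, 1)
    # the bilinear objective is non-decreasing over alternations
    expect_true(all(diff(comp$objective) >= -1e-10))
  }
})

test_that("deflation removes a rank-1 structure completely", {
  sim <- generate_paired_views(n = 30, p1 = 60, p2 = 60, s1 = 8, s2 = 8,
                               noise_sd = 0, seed = 5)
  fit <- suppressWarnings(scca(sim$X1, sim$X2, c1 = 1, c2 = 1,
                               n_components = 2, nonnegative = TRUE))
  expect_equal(fit$q[1], 1, tolerance = 1e-3)
  if (fit$n_components == 2) {
    expect_lt(abs(fit$q_raw[2]), 1e-6 * abs(fit$q_raw[1]))
  }
  # noiseless off-support columns are constant zero and get dropped, so the
  # retained features are exactly the true support
  expect_setequal(fit$X1$retained, sim$truth[[1]]$support1)
})

test_that("a single-component fit reproduces the rank-1 solver", {
  vs <- random_views(25, 12, 9, seed = 21)
  fit <- scca(vs$X1, vs$X2, c1 = 0.6, c2 = 0.7, n_components = 1)
  comp <- scca_rank1(vs$X1, vs$X2, c1 = 0.6, c2 = 0.7)
  expect_identical(fit$components[[1]]$u, comp$u)
  expect_identical(fit$components[[1]]$v, comp$v)
  expect_identical(fit$q_raw, comp$q_raw)
})

test_that("matrix-free deflated products equal explicit deflated products", {
  vs <- random_views(30, 25, 18, seed = 31)
  fit <- suppressWarnings(scca(vs$X1, vs$X2, c1 = 0.6, c2 = 0.6,
                               n_components = 2))
  Zdef <- crossprod(vs$X1$data, vs$X2$data)
  for (i in seq_len(fit$n_components)) {
    cmp <- fit$components[[i]]
    Zdef <- Zdef - cmp$q_raw * tcrossprod(cmp$u, cmp$v)
  }
  set.seed(1)
  for (rep in 1:5) {
    w2 <- rnorm(ncol(vs$X2$data))
    w1 <- rnorm(ncol(vs$X1$data))
    expect_equal(deflated_product(vs$X1, vs$X2, w2, state = fit$state),
                 as.numeric(Zdef %*% w2), tolerance = 1e-10)
    expect_equal(deflated_product(vs$X1, vs$X2, w1, state = fit$state,
                                  transpose = TRUE),
                 as.numeric(crossprod(Zdef, w1)), tolerance = 1e-10)
  }
})

test_that("sparsity is empirically monotone in c on fixed instances", {
  grid <- seq(0.3, 0.9, by = 0.1)
  for (seed in 1:3) {
    sim <- generate_paired_views(n = 40, p1 = 120, p2 = 120, s1 = 8, s2 = 8,
                                 seed = seed)
    X1 <- standardize_columns(sim$X1)
    X2 <- standardize_columns(sim$X2)
    nnz <- vapply(grid, function(c1) {
      suppressWarnings(scca_rank1(X1, X2, c1 = c1, c2 = 0.5))$n_nonzero_u
    }, numeric(1))
    expect_true(all(diff(nnz) >= 0))
  }
})

test_that("canonical correlations handle perfect, null and degenerate cases", {
  vs <- random_views(30, 6, 6, seed = 41)
  u <- rep(1 / sqrt(6), 6)
  expect_equal(as.numeric(canonical_correlation(vs$X1, u, vs$X1, u)), 1)
  expect_equal(as.numeric(canonical_correlation(vs$X1, u, vs$X1, -u)), -1)

  q0 <- canonical_correlation(vs$X1, rep(0, 6), vs$X2, u)
  expect_equal(as.numeric(q0), 0)
  expect_true(attr(q0, "flagged"))

  big <- random_views(1000, 3, 3, seed = 43)
  set.seed(44)
  q <- canonical_correlation(big$X1, rnorm(3), big$X2, rnorm(3))
  expect_lt(abs(as.numeric(q)), 0.1)
})

test_that("views with mismatched sample counts are rejected", {
  expect_error(
    scca_rank1(matrix(rnorm(20), 10, 2), matrix(rnorm(22), 11, 2)),
    "same number of rows"
  )
  expect_error(scca_rank1(matrix(rnorm(20), 10, 2),
                          matrix(rnorm(20), 10, 2), c1 = 1.5),
               "c1")
})

test_that("supports are recovered when the L1 budget matches the truth", {
  # a unit-L2 vector with ||w||_1 = c*sqrt(p) has at least (c*sqrt(p))^2
  # nonzeros, so clean recovery of an S-sparse truth needs c near sqrt(S/p);
  # here S = 10, p = 500 => c ~ 0.15
  sens <- spec <- numeric(5)
  for (s in 1:5) {
    sim <- generate_paired_views(seed = 40 + s)
    X1 <- standardize_columns(sim$X1)
    X2 <- standardize_columns(sim$X2)
    cmp <- suppressWarnings(scca_rank1(X1, X2, c1 = 0.15, c2 = 0.15))
    mu <- support_metrics(inflate_weights(cmp$u, X1), sim$truth[[1]]$support1)
    mv <- support_metrics(inflate_weights(cmp$v, X2), sim$truth[[1]]$support2)
    sens[s] <- mean(c(mu["sensitivity"], mv["sensitivity"]))
    spec[s] <- mean(c(mu["specificity"], mv["specificity"]))
  }
  expect_gte(mean(sens), 0.8)
  expect_gte(mean(spec), 0.95)
})
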