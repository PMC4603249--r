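# Shared fixtures and independent oracle implementations for the test suite.
# Oracles are deliberately written without reusing the package's code paths
# (plain R, brute-force bisection, dense linear algebra).

# Independent soft-threshold (operator definition, written out directly).
oracle_soft <- function(a, delta, nonneg = FALSE) {
  if (nonneg) pmax(a - delta, 0) else sign(a) * pmax(abs(a) - delta, 0)
}

# Independent L2/L1 projection: scalar bisection on the threshold at 1e-10
# resolution. Assumes no exact ties among the leading magnitudes.
oracle_l1_project <- function(a, s, nonneg = FALSE) {
  b <- if (nonneg) pmax(a, 0) else a
  stopifnot(any(b != 0))
  w0 <- b / sqrt(sum(b^2))
  if (sum(abs(w0)) <= s) return(w0)
  l1_of <- function(d) {
    x <- oracle_soft(b, d, nonneg)
    n2 <- sqrt(sum(x^2))
    if (n2 == 0) 0 else sum(abs(x)) / n2
  }
  lo <- 0
  hi <- max(abs(b))
  while (hi - lo > 1e-10 * max(abs(b))) {
    mid <- (lo + hi) / 2
    if (l1_of(mid) > s) lo <- mid else hi <- mid
  }
  x <- oracle_soft(b, (lo + hi) / 2, nonneg)
  x / sqrt(sum(x^2))
}

# Random standardized view pair for solver tests.
random_views <- function(n, p1, p2, seed) {
  set.seed(seed)
  list(
    X1 = standardize_columns(matrix(rnorm(n * p1), n, p1)),
    X2 = standardize_columns(matrix(rnorm(n * p2), n, p2))
  )
}

# Multi-component SCCA on the explicitly formed and explicitly deflated
# cross-product matrix. Mirrors the package's update rules (same projection
# kernel, same initialization policy) but all products go through the dense
# Z, providing the oracle for the matrix-free deflation machinery.
explicit_fit <- function(X1, X2, c1, c2, nonnegative, n_components,
                         max_iter = 2000, tol = 1e-10, power_iter = 20) {
  Z <- crossprod(X1$data, X2$data)
  p1 <- ncol(X1$data)
  p2 <- ncol(X2$data)
  s1 <- c1 * sqrt(p1)
  s2 <- c2 * sqrt(p2)
  comps <- vector("list", n_components)
  for (comp in seq_len(n_components)) {
    v <- scca:::default_v_start(p2, 0)
    v <- v / sqrt(sum(v^2))
    for (t in seq_len(power_iter)) {
      z <- crossprod(Z, Z %*% v)
      nz <- sqrt(sum(z^2))
      if (nz == 0) break
      v <- as.numeric(z / nz)
    }
    if (nonnegative) {
      v <- abs(v)
    } else if (v[which.max(abs(v))] < 0) {
      v <- -v
    }
    u_old <- rep(0, p1)
    v_old <- v
    u <- u_old
    for (iter in seq_len(max_iter)) {
      u_new <- as.numeric(l1_project(Z %*% v, s1, nonnegative))
      v_new <- as.numeric(l1_project(crossprod(Z, u_new), s2, nonnegative))
      du <- max(abs(u_new - u_old))
      dv <- max(abs(v_new - v_old))
      u <- u_new
      v <- v_new
      if (iter > 1 && max(du, dv) < tol) break
      u_old <- u_new
      v_old <- v_new
    }
    q_raw <- as.numeric(crossprod(u, Z %*% v))
    comps[[comp]] <- list(u = u, v = v, q_raw = q_raw, Z_before = Z)
    Z <- Z - q_raw * tcrossprod(u, v)
  }
  comps
}

# Run the packaged command-line interface in a fresh R process.
run_cli <- function(args, quiet = TRUE) {
  script <- system.file("cli", "scca.R", package = "scca")
  stopifnot(nzchar(script))
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(
    rscript, c(script, args),
    stdout = if (quiet) TRUE else "", stderr = if (quiet) TRUE else "",
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  ))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}

# Digest of a file's bytes, for byte-identity checks.
file_md5 <- function(paths) unname(tools::md5sum(paths))
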