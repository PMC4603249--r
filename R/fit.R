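# Rank-1 sparse CCA solver and multi-component fitting by matrix-free
# deflation.  The cross-product matrix Z = X1'X2 is never formed: all
# products are computed as X1'(X2 v) plus rank-1 deflation corrections,
# costing O(n (p1 + p2)) per product.

empty_deflation_state <- function(p1, p2) {
  list(
    d = numeric(0),
    U = matrix(0, nrow = p1, ncol = 0),
    V = matrix(0, nrow = p2, ncol = 0)
  )
}

# Deterministic start vector for the power-iteration initialization.
default_v_start <- function(p2, init_seed = 0) {
  with_local_seed(derive_seed(init_seed, 97), rnorm(p2))
}

#' Product with the deflated cross-product matrix, matrix-free
#'
#' Computes `Z_def w` (or `t(Z_def) w`) where
#' `Z_def = t(X1) %*% X2 - sum_i d_i u_i t(v_i)` without ever forming
#' `Z_def`, using the factored form `t(X1) (X2 w)` plus rank-1 corrections.
#'
#' @param X1,X2 standardized views ([`scca_view`][standardize_columns] or
#'   matrices, standardized on the fly).
#' @param state deflation state as returned in `scca_fit$state`: a list with
#'   `d` (bilinear scores), `U`, `V` (prior canonical vectors, column-wise);
#'   `NULL` for no deflation.
#' @param w numeric vector, length `p2` (or `p1` when `transpose = TRUE`).
#' @param transpose logical; compute `t(Z_def) w` instead.
#' @return numeric vector.
#' @export
deflated_product <- function(X1, X2, w, state = NULL, transpose = FALSE) {
  X1 <- as_scca_view(X1)
  X2 <- as_scca_view(X2)
  if (is.null(state)) state <- empty_deflation_state(ncol(X1$data), ncol(X2$data))
  as.numeric(deflated_product_cpp(
    X1$data, X2$data, state$U, state$V, state$d,
    as.numeric(w), isTRUE(transpose)
  ))
}

#' Canonical correlation of a pair of weight vectors
#'
#' Pearson correlation of the canonical variables `X1 u` and `X2 v`. When
#' either projection has zero variance (e.g., an all-zero weight vector from
#' an over-sparse fit) the correlation is undefined; the value 0 is returned
#' with attribute `flagged = TRUE` so grid searches can score such settings
#' without failing.
#'
#' @param X1,X2 views (standardized matrices or `scca_view` objects).
#' @param u,v weight vectors over the retained columns of `X1`, `X2`.
#' @return correlation in `[-1, 1]`; attribute `flagged` is `TRUE` when the
#'   value was undefined and substituted by 0.
#' @export
canonical_correlation <- function(X1, u, X2, v) {
  X1 <- as_scca_view(X1)
  X2 <- as_scca_view(X2)
  z1 <- as.numeric(X1$data %*% u)
  z2 <- as.numeric(X2$data %*% v)
  if (sd(z1) == 0 || sd(z2) == 0) {
    return(structure(0, flagged = TRUE))
  }
  structure(as.numeric(cor(z1, z2)), flagged = FALSE)
}

#' Rank-1 sparse canonical correlation fit
#'
#' Solves `max_{u,v} t(u) Z_def v` subject to `||u||_2 <= 1, ||v||_2 <= 1`,
#' `||u||_1 <= c1 sqrt(p1)`, `||v||_1 <= c2 sqrt(p2)` (and optionally
#' `u, v >= 0`) by alternating soft-threshold projections, where `Z_def` is
#' the cross-product matrix of the standardized views deflated by any prior
#' components in `state`. `v` is initialized at the leading right singular
#' direction of `Z_def`, estimated by a seeded power iteration.
#'
#' @param X1,X2 views; plain matrices are standardized first.
#' @param c1,c2 per-view sparsity parameters in `(0, 1]`; the effective L1
#'   bound on view k is `c_k * sqrt(p_k)`, so the grid `0.3 ... 0.9` is
#'   comparable across views of different dimension.
#' @param nonnegative restrict weights to be nonnegative (default `TRUE`),
#'   so each canonical variable is a sparse weighted average of features.
#' @param max_iter,tol alternation stops when the largest elementwise change
#'   in `u` and `v` falls below `tol` or after `max_iter` iterations.
#' @param state deflation state from previous components (`NULL` = none).
#' @param v_init optional start vector for the initialization (length `p2`
#'   over retained columns); overrides the seeded default.
#' @param init_seed seed for the default random start of the power iteration.
#' @param power_iter number of power-iteration steps in the initialization.
#' @return object of class `scca_component`: list with unit-norm sparse
#'   weight vectors `u`, `v`; `q` (Pearson canonical correlation, 0 and
#'   flagged when degenerate); `q_raw` (the bilinear score `t(u) Z_def v`,
#'   used for deflation); `n_nonzero_u`, `n_nonzero_v`; `index`;
#'   `iterations`, `converged`, `degenerate`; and `objective`, the bilinear
#'   score after each alternation (non-decreasing).
#' @examples
#' sim <- generate_paired_views(n = 30, p1 = 40, p2 = 40, s1 = 5, s2 = 5,
#'                              seed = 7)
#' comp <- scca_rank1(sim$X1, sim$X2, c1 = 0.5, c2 = 0.5)
#' comp$q
#' @export
scca_rank1 <- function(X1, X2, c1 = 0.5, c2 = 0.5, nonnegative = TRUE,
                       max_iter = 100L, tol = 1e-6, state = NULL,
                       v_init = NULL, init_seed = 0, power_iter = 20L) {
  X1 <- as_scca_view(X1)
  X2 <- as_scca_view(X2)
  n <- nrow(X1$data)
  if (nrow(X2$data) != n) stop("views must have the same number of rows")
  check_c <- function(c, nm) {
    if (!is.numeric(c) || length(c) != 1 || !is.finite(c) || c <= 0 || c > 1) {
      stop(sprintf("%s must lie in (0, 1]", nm))
    }
  }
  check_c(c1, "c1")
  check_c(c2, "c2")
  if (max_iter < 1) stop("max_iter must be a positive integer")
  if (!(tol > 0)) stop("tol must be positive")
  p1 <- ncol(X1$data)
  p2 <- ncol(X2$data)
  if (is.null(state)) state <- empty_deflation_state(p1, p2)
  if (is.null(v_init)) v_init <- default_v_start(p2, init_seed)
  if (length(v_init) != p2) stop("v_init must have length ncol(X2$data)")

  res <- scca_rank1_cpp(
    X1$data, X2$data, c1, c2, isTRUE(nonnegative),
    as.integer(max_iter), tol, as.numeric(v_init), as.integer(power_iter),
    state$U, state$V, state$d
  )
  if (!res$converged && !res$degenerate) {
    warning(sprintf("rank-1 SCCA did not converge in %d iterations", max_iter))
  }
  q <- if (res$degenerate) structure(0, flagged = TRUE) else {
    canonical_correlation(X1, res$u, X2, res$v)
  }
  structure(
    list(
      u = as.numeric(res$u),
      v = as.numeric(res$v),
      q = as.numeric(q),
      q_flagged = isTRUE(attr(q, "flagged")),
      q_raw = res$q_raw,
      index = length(state$d) + 1L,
      n_nonzero_u = sum(res$u != 0),
      n_nonzero_v = sum(res$v != 0),
      iterations = res$iterations,
      converged = res$converged,
      degenerate = res$degenerate,
      objective = as.numeric(res$objective),
      c1 = c1, c2 = c2, nonnegative = isTRUE(nonnegative)
    ),
    class = "scca_component"
  )
}

#' @export
print.scca_component <- function(x, ...) {
  cat(sprintf(
    "<scca_component %d> q = %.4f, q_raw = %.4f, nnz(u) = %d, nnz(v) = %d%s\n",
    x$index, x$q, x$q_raw, x$n_nonzero_u, x$n_nonzero_v,
    if (x$degenerate) " [degenerate]" else ""
  ))
  invisible(x)
}

#' Sparse canonical correlation analysis with deflation
#'
#' Extracts `n_components` pairs of sparse canonical vectors. After each
#' rank-1 fit the cross-product matrix is deflated by the extracted rank-1
#' term, `Z <- Z - q_raw u t(v)` (held implicitly; the deflated matrix is
#' never formed), and the solver is re-run on the residual structure.
#' Successive canonical-vector pairs are not orthogonal in general because
#' of the sparsity constraints.
#'
#' @inheritParams scca_rank1
#' @param n_components number of canonical-vector pairs to extract.
#' @return object of class `scca_fit`: list with `components` (list of
#'   [`scca_component`][scca_rank1]), `q`, `q_raw`, `n_components` (number
#'   actually extracted; extraction stops early, with a warning, if a
#'   component degenerates), `state` (the accumulated deflation state),
#'   `X1`, `X2` (the standardized views), and the parameters used.
#' @examples
#' sim <- generate_paired_views(n = 30, p1 = 40, p2 = 40, s1 = 5, s2 = 5,
#'                              seed = 7)
#' fit <- scca(sim$X1, sim$X2, c1 = 0.5, c2 = 0.5, n_components = 2)
#' fit
#' @export
scca <- function(X1, X2, c1 = 0.5, c2 = 0.5, n_components = 1L,
                 nonnegative = TRUE, max_iter = 100L, tol = 1e-6,
                 init_seed = 0, power_iter = 20L) {
  X1 <- as_scca_view(X1)
  X2 <- as_scca_view(X2)
  if (n_components < 1) stop("n_components must be >= 1")
  p1 <- ncol(X1$data)
  p2 <- ncol(X2$data)
  state <- empty_deflation_state(p1, p2)
  components <- vector("list", 0L)

  for (i in seq_len(n_components)) {
    comp <- scca_rank1(
      X1, X2, c1 = c1, c2 = c2, nonnegative = nonnegative,
      max_iter = max_iter, tol = tol, state = state,
      init_seed = init_seed, power_iter = power_iter
    )
    if (comp$degenerate) {
      warning(sprintf(
        "component %d is degenerate; stopping after %d component(s)",
        i, i - 1L
      ))
      break
    }
    components[[i]] <- comp
    state$d <- c(state$d, comp$q_raw)
    state$U <- cbind(state$U, comp$u)
    state$V <- cbind(state$V, comp$v)
  }

  structure(
    list(
      components = components,
      q = vapply(components, `[[`, numeric(1), "q"),
      q_raw = vapply(components, `[[`, numeric(1), "q_raw"),
      n_components = length(components),
      state = state,
      X1 = X1, X2 = X2,
      c1 = c1, c2 = c2, nonnegative = isTRUE(nonnegative),
      max_iter = max_iter, tol = tol, init_seed = init_seed
    ),
    class = "scca_fit"
  )
}

#' @export
print.scca_fit <- function(x, ...) {
  cat(sprintf(
    "Sparse CCA fit: %d component(s), c1 = %.3g, c2 = %.3g, %s weights\n",
    x$n_components, x$c1, x$c2,
    if (x$nonnegative) "nonnegative" else "signed"
  ))
  if (x$n_components > 0) {
    tab <- data.frame(
      component = seq_len(x$n_components),
      q = round(x$q, 4),
      q_raw = round(x$q_raw, 4),
      nnz_u = vapply(x$components, `[[`, numeric(1), "n_nonzero_u"),
      nnz_v = vapply(x$components, `[[`, numeric(1), "n_nonzero_v")
    )
    print(tab, row.names = FALSE)
  }
  invisible(x)
}
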