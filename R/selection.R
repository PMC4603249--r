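# Permutation-based, per-view-independent selection of the sparsity
# parameters (c1, c2) over a grid, scored by a Fisher-transformed
# z-statistic against a permutation null.

#' Fisher z-transformation of a correlation
#'
#' `atanh(q)`, with `|q|` clamped at `1 - 1e-12` first so that degenerate
#' perfect correlations map to a large finite value rather than infinity.
#'
#' @param q numeric vector of correlations in `[-1, 1]`.
#' @return numeric vector of transformed values.
#' @export
fisher_z <- function(q) {
  if (any(!is.finite(q)) || any(abs(q) > 1 + 1e-8)) {
    stop("correlations must lie in [-1, 1]")
  }
  q <- pmin(pmax(q, -1), 1)
  lim <- 1 - 1e-12
  atanh(pmin(pmax(q, -lim), lim))
}

#' Permutation z-statistic for an observed canonical correlation
#'
#' `z = (Fisher(q_obs) - mean(Fisher(q_null))) / sd(Fisher(q_null))`, with
#' the sample standard deviation (denominator n - 1). A zero-spread null
#' yields a signed largest-finite-value substitute with a warning.
#'
#' @param q_obs observed canonical correlation.
#' @param q_null numeric vector (length >= 2, at least 2 distinct values
#'   expected) of canonical correlations from permuted data.
#' @return the z-statistic (finite).
#' @export
z_statistic <- function(q_obs, q_null) {
  if (length(q_null) < 2) stop("q_null must contain at least 2 values")
  fz_null <- fisher_z(q_null)
  s <- sd(fz_null)
  delta <- fisher_z(q_obs) - mean(fz_null)
  if (s == 0) {
    warning("zero spread in permutation null; z replaced by largest finite value")
    return(sign(delta) * .Machine$double.xmax)
  }
  delta / s
}

# Shared core: rank-1 canonical correlations on permuted views. `perms` is a
# list of lists with integer permutations `i1`, `i2`; views must already be
# standardized. Returns the correlations with the degenerate count attached.
null_correlations <- function(X1, X2, c1, c2, perms, nonnegative = TRUE,
                              max_iter = 100L, tol = 1e-6, init_seed = 0,
                              power_iter = 20L) {
  v_start <- default_v_start(ncol(X2$data), init_seed)
  q <- numeric(length(perms))
  n_degenerate <- 0L
  Y1 <- X1
  Y2 <- X2
  for (j in seq_along(perms)) {
    Y1$data <- X1$data[perms[[j]]$i1, , drop = FALSE]
    Y2$data <- X2$data[perms[[j]]$i2, , drop = FALSE]
    comp <- suppressWarnings(scca_rank1(
      Y1, Y2, c1 = c1, c2 = c2, nonnegative = nonnegative,
      max_iter = max_iter, tol = tol, v_init = v_start,
      power_iter = power_iter
    ))
    if (comp$degenerate || comp$q_flagged) n_degenerate <- n_degenerate + 1L
    q[j] <- comp$q
  }
  structure(q, n_degenerate = n_degenerate)
}

draw_permutations <- function(n, k, seed, stream = 0L) {
  lapply(seq_len(k), function(j) {
    list(
      i1 = with_local_seed(derive_seed(seed, stream, j, 1), sample.int(n)),
      i2 = with_local_seed(derive_seed(seed, stream, j, 2), sample.int(n))
    )
  })
}

#' Permutation null distribution of the first canonical correlation
#'
#' Repeatedly permutes the rows of the two views independently (breaking the
#' sample pairing), refits the first sparse canonical component at fixed
#' `(c1, c2)`, and records the canonical correlation. Degenerate fits
#' contribute 0 and are counted in attribute `n_degenerate`.
#'
#' @inheritParams scca_rank1
#' @param k number of permutations.
#' @param seed integer seed governing all permutations.
#' @return numeric vector of `k` null correlations with attribute
#'   `n_degenerate`.
#' @export
scca_null_distribution <- function(X1, X2, c1, c2, k = 1000L, seed = 1,
                                   nonnegative = TRUE, max_iter = 100L,
                                   tol = 1e-6, init_seed = 0,
                                   power_iter = 20L) {
  if (k < 1) stop("k must be >= 1")
  X1 <- as_scca_view(X1)
  X2 <- as_scca_view(X2)
  n <- nrow(X1$data)
  if (nrow(X2$data) != n) stop("views must have the same number of rows")
  perms <- draw_permutations(n, k, seed)
  null_correlations(
    X1, X2, c1, c2, perms, nonnegative = nonnegative,
    max_iter = max_iter, tol = tol, init_seed = init_seed,
    power_iter = power_iter
  )
}

#' Permutation grid search for the per-view sparsity parameters
#'
#' Scores every `(c1, c2)` pair on a grid by the z-statistic of the observed
#' first canonical correlation against its permutation null (the same `k`
#' permutation pairs are reused across grid cells, so cells are compared on
#' identical resamplings) and picks the pair with the highest z. Only the
#' first canonical component enters the selection. The final model is then
#' refit on the original data at the chosen pair.
#'
#' Allowing `c1` and `c2` to differ lets each view receive its own degree of
#' sparsity -- important when the views have different numbers of truly
#' contributing features.
#'
#' @inheritParams scca_null_distribution
#' @param grid1,grid2 candidate values in `(0, 1]` for `c1` and `c2`.
#' @param n_components number of components for the final refit.
#' @return object of class `scca_selection`: list with `grid1`, `grid2`,
#'   `q_obs` and `z` matrices (`length(grid1)` x `length(grid2)`), `table`
#'   (long-format data frame with columns c1, c2, q_obs, z), `chosen`
#'   (named vector c1, c2), `k`, `seed`, `n_degenerate_null` (matrix), and
#'   `fit`, the final [scca()] refit at the chosen pair. Ties on z are
#'   broken toward larger `c1 + c2`, then larger `c1` (denser solutions).
#' @examples
#' sim <- generate_paired_views(n = 30, p1 = 40, p2 = 40, s1 = 5, s2 = 5,
#'                              seed = 7)
#' sel <- scca_select(sim$X1, sim$X2, grid1 = c(0.4, 0.7),
#'                    grid2 = c(0.4, 0.7), k = 20, seed = 1)
#' sel$chosen
#' @export
scca_select <- function(X1, X2, grid1 = seq(0.3, 0.9, by = 0.1),
                        grid2 = seq(0.3, 0.9, by = 0.1), k = 1000L,
                        seed = 1, nonnegative = TRUE, n_components = 1L,
                        max_iter = 100L, tol = 1e-6, init_seed = 0,
                        power_iter = 20L) {
  if (length(grid1) < 1 || length(grid2) < 1) stop("grids must be non-empty")
  if (any(grid1 <= 0 | grid1 > 1) || any(grid2 <= 0 | grid2 > 1)) {
    stop("grid values must lie in (0, 1]")
  }
  if (k < 2) stop("k must be >= 2 to estimate the null spread")
  X1 <- as_scca_view(X1)
  X2 <- as_scca_view(X2)
  n <- nrow(X1$data)
  if (nrow(X2$data) != n) stop("views must have the same number of rows")

  perms <- draw_permutations(n, k, seed)
  n1 <- length(grid1)
  n2 <- length(grid2)
  q_obs <- matrix(NA_real_, n1, n2, dimnames = list(grid1, grid2))
  zmat <- q_obs
  ndeg <- matrix(0L, n1, n2, dimnames = list(grid1, grid2))
  obs_flagged <- matrix(FALSE, n1, n2)

  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      comp <- suppressWarnings(scca_rank1(
        X1, X2, c1 = grid1[i], c2 = grid2[j], nonnegative = nonnegative,
        max_iter = max_iter, tol = tol, init_seed = init_seed,
        power_iter = power_iter
      ))
      q_obs[i, j] <- comp$q
      obs_flagged[i, j] <- comp$degenerate || comp$q_flagged
      qn <- null_correlations(
        X1, X2, grid1[i], grid2[j], perms, nonnegative = nonnegative,
        max_iter = max_iter, tol = tol, init_seed = init_seed,
        power_iter = power_iter
      )
      ndeg[i, j] <- attr(qn, "n_degenerate")
      zmat[i, j] <- suppressWarnings(z_statistic(q_obs[i, j], qn))
    }
  }

  if (all(obs_flagged)) {
    stop("all grid cells produced degenerate fits; no parameters selectable")
  }

  zrank <- zmat
  zrank[obs_flagged] <- -Inf
  best <- which(zrank == max(zrank), arr.ind = TRUE)
  if (nrow(best) > 1) {
    csum <- grid1[best[, 1]] + grid2[best[, 2]]
    best <- best[csum == max(csum), , drop = FALSE]
    if (nrow(best) > 1) {
      c1v <- grid1[best[, 1]]
      best <- best[which.max(c1v), , drop = FALSE]
    }
  }
  chosen <- c(c1 = grid1[best[1, 1]], c2 = grid2[best[1, 2]])

  fit <- scca(
    X1, X2, c1 = chosen[["c1"]], c2 = chosen[["c2"]],
    n_components = n_components, nonnegative = nonnegative,
    max_iter = max_iter, tol = tol, init_seed = init_seed,
    power_iter = power_iter
  )

  structure(
    list(
      grid1 = grid1, grid2 = grid2, q_obs = q_obs, z = zmat,
      table = data.frame(
        c1 = rep(grid1, times = n2),
        c2 = rep(grid2, each = n1),
        q_obs = as.vector(q_obs),
        z = as.vector(zmat)
      ),
      chosen = chosen, k = k, seed = seed,
      n_degenerate_null = ndeg, obs_flagged = obs_flagged,
      fit = fit
    ),
    class = "scca_selection"
  )
}

#' @export
print.scca_selection <- function(x, ...) {
  cat(sprintf(
    "SCCA parameter selection over a %d x %d grid (k = %d permutations)\n",
    length(x$grid1), length(x$grid2), x$k
  ))
  cat(sprintf(
    "chosen: c1 = %.3g, c2 = %.3g (z = %.2f, q = %.4f)\n",
    x$chosen[["c1"]], x$chosen[["c2"]],
    x$z[as.character(x$chosen[["c1"]]), as.character(x$chosen[["c2"]])],
    x$q_obs[as.character(x$chosen[["c1"]]), as.character(x$chosen[["c2"]])]
  ))
  invisible(x)
}
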