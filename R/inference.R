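#' Permutation p-values for canonical correlations
#'
#' Tests the significance of the first `m` canonical correlations at fixed
#' sparsity parameters. The observed fit extracts `m` components by
#' deflation; each of `k` permutation replicates independently permutes the
#' rows of both views (destroying the sample pairing) and refits the full
#' `m`-component model, and component `i`'s null is the set of `i`-th
#' canonical correlations across replicates. The one-sided p-value uses the
#' add-one permutation form `(#\{q_null >= q_obs\} + 1) / (k + 1)`, which is
#' never exactly zero.
#'
#' @inheritParams scca_rank1
#' @param m number of components to test.
#' @param k number of permutation replicates.
#' @param seed integer seed governing all permutations.
#' @return object of class `scca_significance`: a data frame with columns
#'   `component`, `q` (observed canonical correlation), `exceed` (number of
#'   null values >= observed), `k`, and `p_value`. If the observed fit
#'   degenerates at component `i`, components `i..m` are reported with
#'   `p_value = 1`. The matrix of null correlations is attached as attribute
#'   `"null"` (k x m).
#' @examples
#' sim <- generate_paired_views(n = 30, p1 = 40, p2 = 40, s1 = 5, s2 = 5,
#'                              seed = 7)
#' scca_significance(sim$X1, sim$X2, c1 = 0.5, c2 = 0.5, m = 2, k = 49,
#'                   seed = 1)
#' @export
scca_significance <- function(X1, X2, c1 = 0.5, c2 = 0.5, m = 1L, k = 1000L,
                              seed = 1, nonnegative = TRUE, max_iter = 100L,
                              tol = 1e-6, init_seed = 0, power_iter = 20L) {
  if (m < 1) stop("m must be >= 1")
  if (k < 1) stop("k must be >= 1")
  X1 <- as_scca_view(X1)
  X2 <- as_scca_view(X2)
  n <- nrow(X1$data)
  if (nrow(X2$data) != n) stop("views must have the same number of rows")

  fit_m <- function(Y1, Y2) {
    f <- suppressWarnings(scca(
      Y1, Y2, c1 = c1, c2 = c2, n_components = m,
      nonnegative = nonnegative, max_iter = max_iter, tol = tol,
      init_seed = init_seed, power_iter = power_iter
    ))
    q <- rep(NA_real_, m)
    if (f$n_components > 0) q[seq_len(f$n_components)] <- f$q
    q
  }

  q_obs <- fit_m(X1, X2)
  if (anyNA(q_obs)) {
    warning(sprintf(
      "observed fit degenerated after %d component(s); remaining components reported with p = 1",
      sum(!is.na(q_obs))
    ))
  }

  # fresh permutation streams, distinct from those used by scca_select
  perms <- draw_permutations(n, k, seed, stream = 7919L)
  q_null <- matrix(NA_real_, nrow = k, ncol = m)
  Y1 <- X1
  Y2 <- X2
  for (j in seq_len(k)) {
    Y1$data <- X1$data[perms[[j]]$i1, , drop = FALSE]
    Y2$data <- X2$data[perms[[j]]$i2, , drop = FALSE]
    q_null[j, ] <- fit_m(Y1, Y2)
  }
  q_null[is.na(q_null)] <- 0  # degenerate replicate components score 0

  exceed <- integer(m)
  p <- numeric(m)
  for (i in seq_len(m)) {
    if (is.na(q_obs[i])) {
      exceed[i] <- k
      p[i] <- 1
    } else {
      exceed[i] <- sum(q_null[, i] >= q_obs[i])
      p[i] <- (exceed[i] + 1) / (k + 1)
    }
  }

  out <- data.frame(
    component = seq_len(m),
    q = ifelse(is.na(q_obs), 0, q_obs),
    exceed = exceed,
    k = k,
    p_value = p
  )
  attr(out, "null") <- q_null
  class(out) <- c("scca_significance", "data.frame")
  out
}

#' @export
print.scca_significance <- function(x, ...) {
  cat(sprintf("Permutation test of canonical correlations (k = %d)\n", x$k[1]))
  df <- as.data.frame(x)
  df$q <- round(df$q, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
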