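# Synthetic paired-view generator: two views share sparse nonnegative
# latent spatial patterns plus independent Gaussian noise.  Stands in for
# paired imaging conditions (e.g., two drug-minus-placebo perfusion
# contrasts on the same subjects) in tests, calibration and benchmarks.

#' Generate paired views sharing sparse latent factors
#'
#' For each factor `f`, a latent score vector (standard normal across the
#' `n` samples) loads onto a sparse nonnegative unit-L2 loading vector in
#' each view: `X_k <- X_k + signal * latent_f %*% t(loading_fk)`. Supports
#' of distinct factors are disjoint within a view, and support sizes may
#' differ between views (asymmetric sparsity). Independent Gaussian noise of
#' standard deviation `noise_sd` is then added to both views.
#'
#' The defaults (`n = 50`, `p = 500`, supports of 10, `signal = 3`,
#' `noise_sd = 1`) give a population canonical correlation of about
#' `signal^2 / (signal^2 + 1) = 0.9` along the true loadings, comparable to
#' the strong correlations seen in paired pharmacological imaging contrasts.
#'
#' @param n number of samples (>= 3).
#' @param p1,p2 number of features per view.
#' @param s1,s2 support size (number of nonzero loadings) per view and
#'   factor; `n_factors * s_k` must not exceed `p_k`.
#' @param signal scale of the shared latent term.
#' @param noise_sd standard deviation of the independent Gaussian noise.
#' @param n_factors number of shared latent factors.
#' @param seed integer seed; the same seed gives bit-identical output.
#' @param nonneg_loadings if `TRUE` (default) nonzero loadings are drawn
#'   uniform on (0.5, 1] before unit-L2 normalization, matching the model's
#'   nonnegativity constraint; otherwise random signs are attached.
#' @param spatial if `TRUE`, supports are contiguous index blocks (emulating
#'   compact clusters when rows are written out as masked volumes) instead
#'   of random positions.
#' @return list with raw (unstandardized) matrices `X1` (n x p1), `X2`
#'   (n x p2) and `truth`, a list with one entry per factor, each holding
#'   `u_true`, `v_true` (unit-L2 nonzero-on-support loading vectors),
#'   `support1`, `support2` (integer index sets), and `latent` (length-n
#'   scores); plus the generator settings.
#' @examples
#' sim <- generate_paired_views(n = 20, p1 = 50, p2 = 50, s1 = 4, s2 = 4,
#'                              seed = 1)
#' str(sim$truth[[1]]$support1)
#' @export
generate_paired_views <- function(n = 50, p1 = 500, p2 = 500, s1 = 10,
                                  s2 = 10, signal = 3, noise_sd = 1,
                                  n_factors = 1L, seed = 1,
                                  nonneg_loadings = TRUE, spatial = FALSE) {
  if (n < 3) stop("n must be >= 3")
  if (n_factors < 1) stop("n_factors must be >= 1")
  if (n_factors * s1 > p1 || n_factors * s2 > p2) {
    stop("disjoint supports infeasible: n_factors * support size exceeds p")
  }
  if (!(signal >= 0) || !(noise_sd >= 0)) {
    stop("signal and noise_sd must be nonnegative")
  }

  with_local_seed(derive_seed(seed, 101), {
    make_loading <- function(p, s, support) {
      w <- numeric(p)
      vals <- runif(s, min = 0.5, max = 1)
      if (!nonneg_loadings) vals <- vals * sample(c(-1, 1), s, replace = TRUE)
      w[support] <- vals
      w / sqrt(sum(w^2))
    }
    pick_support <- function(p, s, f, available) {
      if (spatial) ((f - 1) * s + 1):(f * s) else sort(sample(available, s))
    }

    X1 <- matrix(0, n, p1)
    X2 <- matrix(0, n, p2)
    avail1 <- seq_len(p1)
    avail2 <- seq_len(p2)
    truth <- vector("list", n_factors)
    for (f in seq_len(n_factors)) {
      sup1 <- pick_support(p1, s1, f, avail1)
      sup2 <- pick_support(p2, s2, f, avail2)
      avail1 <- setdiff(avail1, sup1)
      avail2 <- setdiff(avail2, sup2)
      u_true <- make_loading(p1, s1, sup1)
      v_true <- make_loading(p2, s2, sup2)
      latent <- rnorm(n)
      X1 <- X1 + signal * tcrossprod(latent, u_true)
      X2 <- X2 + signal * tcrossprod(latent, v_true)
      truth[[f]] <- list(
        u_true = u_true, v_true = v_true,
        support1 = sup1, support2 = sup2, latent = latent
      )
    }
    if (noise_sd > 0) {
      X1 <- X1 + matrix(rnorm(n * p1, sd = noise_sd), n, p1)
      X2 <- X2 + matrix(rnorm(n * p2, sd = noise_sd), n, p2)
    }
    list(
      X1 = X1, X2 = X2, truth = truth,
      signal = signal, noise_sd = noise_sd, seed = seed,
      n_factors = n_factors
    )
  })
}

#' Generate two independent Gaussian views (global null)
#'
#' Entries are independent standard normal; the views share no structure, so
#' any apparent canonical correlation is sampling noise.
#'
#' @inheritParams generate_paired_views
#' @return list with matrices `X1` (n x p1) and `X2` (n x p2).
#' @export
generate_null_views <- function(n, p1, p2, seed = 1) {
  with_local_seed(derive_seed(seed, 202), {
    list(
      X1 = matrix(rnorm(n * p1), n, p1),
      X2 = matrix(rnorm(n * p2), n, p2)
    )
  })
}

#' Support-recovery metrics for an estimated weight vector
#'
#' Compares the nonzero pattern of an estimated weight vector (in the
#' original feature space; see [inflate_weights()]) against a known true
#' support.
#'
#' @param w estimated weight vector over all `p` original features.
#' @param true_support integer indices of the truly nonzero features.
#' @param tol entries with `|w| > tol` count as selected.
#' @return named numeric vector with `sensitivity` (true positives / true
#'   support size), `specificity` (true negatives / true zeros), and `f1`.
#' @export
support_metrics <- function(w, true_support, tol = 1e-12) {
  p <- length(w)
  est <- which(abs(w) > tol)
  tp <- length(intersect(est, true_support))
  fp <- length(setdiff(est, true_support))
  fn <- length(setdiff(true_support, est))
  tn <- p - tp - fp - fn
  sens <- if (length(true_support) > 0) tp / length(true_support) else NA_real_
  spec <- if (p > length(true_support)) tn / (p - length(true_support)) else NA_real_
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  c(sensitivity = sens, specificity = spec, f1 = f1)
}
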