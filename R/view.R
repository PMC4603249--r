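#' Standardize the columns of a data matrix
#'
#' Centers every column to mean zero and scales it to unit (sample) standard
#' deviation, the form the SCCA objective assumes. Columns with zero variance
#' carry no information for a correlation objective and are dropped; their
#' identities are recorded so weight vectors can later be re-inflated to the
#' original feature space with explicit zeros (see [inflate_weights()]).
#'
#' @param X numeric matrix, n samples (rows) by p features (columns), n >= 2,
#'   all entries finite.
#' @param feature_ids optional character vector of feature labels; defaults to
#'   `colnames(X)` or `"V1" ... "Vp"`.
#' @return An object of class `scca_view`: a list with elements `data` (the
#'   standardized matrix, zero-variance columns removed), `feature_ids`
#'   (labels of retained columns), `retained` (integer positions of retained
#'   columns in the original matrix), `dropped` (labels of dropped columns),
#'   `p_original`, and `standardized = TRUE`.
#' @examples
#' X <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
#' v <- standardize_columns(X)
#' v$data          # column "a" -> (-1, 0, 1); constant column "b" dropped
#' v$dropped
#' @export
standardize_columns <- function(X, feature_ids = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) < 2) stop("at least 2 rows (samples) are required")
  if (ncol(X) < 1) stop("at least 1 column (feature) is required")
  if (!all(is.finite(X))) stop("non-finite entries in input matrix")
  if (is.null(feature_ids)) feature_ids <- colnames(X)
  if (is.null(feature_ids)) feature_ids <- paste0("V", seq_len(ncol(X)))
  if (length(feature_ids) != ncol(X)) {
    stop("feature_ids must have one entry per column")
  }

  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu, "-")
  s <- sqrt(colSums(Xc^2) / (nrow(X) - 1))
  keep <- s > 1e-12 * (abs(mu) + 1)
  if (!any(keep)) stop("no informative features: all columns have zero variance")
  Xs <- sweep(Xc[, keep, drop = FALSE], 2, s[keep], "/")
  dimnames(Xs) <- NULL

  structure(
    list(
      data = Xs,
      feature_ids = feature_ids[keep],
      retained = unname(which(keep)),
      dropped = feature_ids[!keep],
      p_original = ncol(X),
      standardized = TRUE
    ),
    class = "scca_view"
  )
}

# Coerce a matrix (standardizing it) or pass an scca_view through.
as_scca_view <- function(x) {
  if (inherits(x, "scca_view")) return(x)
  standardize_columns(x)
}

#' @export
print.scca_view <- function(x, ...) {
  cat(sprintf(
    "<scca_view> %d samples x %d features (%d of %d columns retained)\n",
    nrow(x$data), ncol(x$data), ncol(x$data), x$p_original
  ))
  invisible(x)
}

#' @export
dim.scca_view <- function(x) dim(x$data)

#' Re-inflate a weight vector to the original feature space
#'
#' Weight vectors are estimated over the columns retained at standardization.
#' This maps such a vector back to the original feature order, writing an
#' explicit zero at every dropped (zero-variance) position -- required, e.g.,
#' to render a canonical vector as a voxel map.
#'
#' @param w numeric vector, one entry per retained column of `view`.
#' @param view an [`scca_view`][standardize_columns].
#' @return numeric vector of length `view$p_original`.
#' @export
inflate_weights <- function(w, view) {
  stopifnot(inherits(view, "scca_view"))
  if (length(w) != length(view$retained)) {
    stop("length(w) must equal the number of retained columns")
  }
  out <- numeric(view$p_original)
  out[view$retained] <- w
  out
}

#' Independently permute the sample rows of two views
#'
#' Draws one uniform random permutation per view and reorders the rows,
#' breaking any sample-level correspondence between the views while leaving
#' each column's marginal moments (hence its standardization) untouched.
#'
#' @param X1,X2 matrices or [`scca_view`][standardize_columns] objects with an
#'   equal number of rows.
#' @param seed integer seed; the same seed reproduces the same permutations.
#' @return list with permuted views `X1` and `X2` (as `scca_view`) and the
#'   permutations used (`perm1`, `perm2`).
#' @export
permute_views <- function(X1, X2, seed = 1) {
  X1 <- as_scca_view(X1)
  X2 <- as_scca_view(X2)
  n <- nrow(X1$data)
  if (nrow(X2$data) != n) stop("views must have the same number of rows")
  perm1 <- with_local_seed(derive_seed(seed, 1), sample.int(n))
  perm2 <- with_local_seed(derive_seed(seed, 2), sample.int(n))
  Y1 <- X1
  Y2 <- X2
  Y1$data <- X1$data[perm1, , drop = FALSE]
  Y2$data <- X2$data[perm2, , drop = FALSE]
  list(X1 = Y1, X2 = Y2, perm1 = perm1, perm2 = perm2)
}
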