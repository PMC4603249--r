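#' Soft-thresholding operator
#'
#' The proximal operator of the L1 penalty. In signed mode each entry is
#' shrunk toward zero: `sign(a) * max(|a| - delta, 0)`. In nonnegative mode
#' negative entries are clipped and positive ones shrunk: `max(a - delta, 0)`.
#'
#' @param a numeric vector.
#' @param delta nonnegative shrinkage amount.
#' @param nonnegative logical; clip instead of shrinking symmetric about 0.
#' @return numeric vector of the same length as `a`.
#' @examples
#' soft_threshold(c(2, -1, 0.3), 0.5)                      # 1.5 -0.5 0.0
#' soft_threshold(c(2, -1, 0.3), 0.5, nonnegative = TRUE)  # 1.5 0.0 0.0
#' @export
soft_threshold <- function(a, delta, nonnegative = FALSE) {
  if (!is.numeric(delta) || length(delta) != 1 || !is.finite(delta) || delta < 0) {
    stop("delta must be a single nonnegative number")
  }
  as.numeric(soft_threshold_cpp(as.numeric(a), delta, isTRUE(nonnegative)))
}

#' Joint L2/L1 projection along the soft-threshold path
#'
#' Returns the unit-L2 vector `w = S(a, delta*) / ||S(a, delta*)||_2` with
#' `||w||_1 <= s`: `delta* = 0` when the L1 constraint is already inactive,
#' otherwise `delta*` is located by bisection so that `||w||_1 = s` (to
#' within 1e-12, at most 100 steps). This is the u- and v-update of the
#' penalized matrix
#' decomposition. With `s < 1` the constraints are jointly infeasible for a
#' unit vector. Ties in the leading magnitudes (where `||w||_1 = s` is
#' unattainable) are broken by retaining the lowest-index entries first.
#'
#' @param a numeric vector, nonzero after optional nonnegative clipping.
#' @param s L1 bound, `s >= 1`.
#' @param nonnegative logical; restrict the result to nonnegative entries.
#' @return unit-L2 numeric vector with `||w||_1 <= s + 1e-6`; the threshold
#'   used is attached as attribute `"delta"`.
#' @examples
#' l1_project(c(3, 4), sqrt(2))   # constraint inactive: c(0.6, 0.8)
#' l1_project(c(1, 1), 1)         # boundary s = 1: single nonzero, index 1
#' @export
l1_project <- function(a, s, nonnegative = FALSE) {
  if (!is.numeric(s) || length(s) != 1 || !is.finite(s) || s < 1) {
    stop("s must be a single number >= 1")
  }
  res <- l1_project_cpp(as.numeric(a), s, isTRUE(nonnegative))
  if (isTRUE(res$degenerate)) {
    stop("degenerate direction: no admissible nonzero entries")
  }
  structure(as.numeric(res$w), delta = res$delta)
}
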