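---
title: "Sparse canonical correlation analysis with permutation-based model selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse canonical correlation analysis with permutation-based model selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scca)
```

## The problem

Intra-modal neuroimaging designs measure the same subjects under several
conditions — for instance, resting cerebral blood flow (ASL) under two
antipsychotic drugs, each expressed as a drug-minus-placebo contrast. Most
multivariate analyses of such designs ask how the conditions *differ*; this
package asks how they are *similar*. Canonical correlation analysis (CCA)
answers that question for a pair of datasets $X_1$ ($n \times p_1$) and
$X_2$ ($n \times p_2$) with matched rows: it finds weight vectors $u, v$
(canonical vectors) such that the canonical variables $X_1 u$ and $X_2 v$
are maximally correlated.

With voxels as features, $p \gg n$ and classical CCA is unusable: the
within-view covariance matrices are singular and the solution is not
unique. The sparse CCA (SCCA) used here makes two modifications. First, each
view's covariance matrix is replaced by its diagonal — the identity after
column standardization ("diagonal penalized CCA"), which makes the problem
well-posed at any dimension. Second, the canonical vectors are constrained
in both L2 and L1 norm:

$$
\max_{u,v}\; u^\top X_1^\top X_2\, v
\quad \text{s.t.} \quad
\|u\|_2^2 \le 1,\; \|v\|_2^2 \le 1,\;
\|u\|_1 \le c_1\sqrt{p_1},\; \|v\|_1 \le c_2\sqrt{p_2},
$$

optionally with $u, v \ge 0$ (the default), so each canonical variable is a
sparse weighted *average* of features and the weight maps read as
nonnegative spatial patterns. This is the penalized matrix decomposition
(PMD) form of SCCA, solved by alternating closed-form updates:
$u \leftarrow \mathcal{P}_{s_1}(Z v)$, $v \leftarrow \mathcal{P}_{s_2}(Z^\top u)$,
where $Z = X_1^\top X_2$ and $\mathcal{P}_s(a)$ soft-thresholds $a$ and
renormalizes to unit L2 norm, with the threshold chosen by bisection so the
L1 bound holds. Each update is the exact maximizer of the bilinear
objective in one block, so the objective is non-decreasing across
iterations — this is asserted on every fit in the test suite.

## Parameterization of the L1 bound

The sparsity parameters $c_1, c_2 \in (0, 1]$ are fractions of the loosest
useful bound: the effective budget for view $k$ is $c_k\sqrt{p_k}$ (a unit-L2
vector's L1 norm is at most $\sqrt{p_k}$). This makes $c$ comparable across
views of different dimension and makes a common grid such as
$\{0.3, 0.4, \ldots, 0.9\}$ meaningful for both views. Two consequences are
worth keeping in mind:

* $c = 1$ does **not** necessarily return the dense (unpenalized) solution,
  because the alternation still passes through the thresholding operator;
  with the constraint inactive it reduces to power iteration on $Z$ and
  recovers the leading singular triple (verified against a dense SVD in the
  tests).
* A unit-L2 vector with $\|w\|_1 = c\sqrt{p}$ has at least $c^2 p$ nonzero
  entries (Cauchy–Schwarz). The budget therefore sets a *floor* on the
  number of selected features: at $c = 0.3$ and $p = 500$ every fitted
  vector has at least 45 nonzeros, regardless of how sparse the underlying
  truth is. When the true support is much smaller than $c^2 p$ for every
  $c$ on the grid, the extra budget is spent on small-weight noise voxels;
  support *sensitivity* is unaffected but specificity saturates below 1.
  Recovering a 10-of-500 support cleanly requires $c \approx
  \sqrt{10/500} \approx 0.15$, below the default grid. The default grid
  follows the range commonly used for imaging data, where true supports are
  thousands of voxels; users hunting very sparse signals should extend the
  grid downward.

## Selecting $c_1$ and $c_2$ by permutation

The two views need not be equally sparse (one drug may affect many more
voxels than another), so the package optimizes $c_1$ and $c_2$
independently over a 2-D grid. For each pair, the rows of both views are
independently permuted $k$ times (breaking the subject pairing while
preserving every column's marginal distribution), the first component is
refit on each permuted dataset, and the observed canonical correlation is
scored against the permutation null on the Fisher-transformed scale:

$$
z_{c_1 c_2} =
\frac{\operatorname{atanh}(q) - \operatorname{mean}(\operatorname{atanh}(\dot q))}
     {\operatorname{sd}(\operatorname{atanh}(\dot q))}.
$$

The pair with the highest $z$ wins, and the final model is refit on the
original (unpermuted) data at that pair. Selection uses only the first
component. Design choices:

* **Shared permutation streams.** The same $k$ permutation pairs are reused
  for every grid cell, so cells are compared on identical resamplings — a
  paired comparison that removes between-cell Monte-Carlo noise from the
  argmax. (Independent streams per cell would also be valid, just noisier.)
* **Sample standard deviation** (denominator $n-1$) in $z$.
* **Clamping.** $|q|$ is clamped at $1 - 10^{-12}$ before
  $\operatorname{atanh}$, so degenerate perfect correlations yield large
  finite $z$ rather than infinities; a zero-spread null returns the largest
  finite value with a warning.
* **Tie-breaking** on the grid prefers larger $c_1 + c_2$, then larger
  $c_1$ — conservative about discarding features.
* **Degenerate fits** (an all-zero weight vector, possible in nonnegative
  mode when no admissible direction exists) score $q = 0$ and are counted,
  so the grid search can traverse over-sparse settings without failing.

## Significance of the canonical correlations

With $(c_1, c_2)$ fixed, the first $m$ components are extracted by
deflation and each permutation replicate refits the full $m$-component
model on independently permuted views; component $i$'s null is the set of
$i$-th correlations across replicates (the procedure for higher components
is not uniquely defined by the alternating algorithm itself; refitting the
whole deflation pipeline under the null preserves the estimation procedure
being tested). The one-sided p-value uses the add-one form
$(\#\{\dot q_i \ge q_i\} + 1)/(k + 1)$, the standard valid permutation-test
estimator; the plain $\#/k$ form can produce exactly zero p-values. At
$k = 1000$ the two differ by less than $10^{-3}$.

## Multiple components and matrix-free deflation

After extracting $(u, v)$ with bilinear score $q_{\mathrm{raw}} = u^\top Z
v$, the cross-product matrix is deflated, $Z \leftarrow Z -
q_{\mathrm{raw}}\, u v^\top$, and the solver is re-run. Successive canonical
vectors are *not* orthogonal in general — the sparsity constraints preclude
it. At imaging scale ($p_1 = p_2 \approx 4 \times 10^4$ voxels), $Z$ has
more than $10^9$ entries and is never formed: all products are computed as
$X_1^\top (X_2 v)$ at cost $O(n(p_1 + p_2))$ plus a rank-1 correction per
extracted component. The deflation score is the bilinear form
$q_{\mathrm{raw}}$, while the reported canonical correlation $q$ is the
Pearson correlation of $X_1 u$ and $X_2 v$ (these coincide only without
penalties); both are kept on every component.

## Numerical choices

* **Initialization:** $v$ starts at the leading right singular direction of
  the (deflated) cross-product matrix, estimated by 20 power iterations from
  a fixed seeded random vector (seed 0 by default); in nonnegative mode the
  elementwise absolute value is taken, which cannot be degenerate. The same
  policy is used for observed and permuted fits.
* **Convergence:** alternation stops when
  $\max(\|u_t - u_{t-1}\|_\infty, \|v_t - v_{t-1}\|_\infty) <$ `tol`
  (default $10^{-6}$) or after `max_iter` (default 100) iterations, with a
  warning in the latter case.
* **Bisection:** the threshold solving $\|w\|_1 = s$ is located to
  $10^{-12}$ on the constraint value, at most 100 halvings. The tight
  tolerance keeps each block update an (effectively) exact maximizer, which
  is what guarantees monotone ascent of the objective. Exact ties among
  leading magnitudes (where $\|w\|_1 = s$ is unattainable) are broken by
  retaining the lowest-index entries first, for reproducibility.
* **Zero-variance columns** are dropped at standardization and re-inflated
  as explicit zeros in exported weight maps.
* **Randomness:** every permutation and initialization derives from a
  user-facing seed through a small mixing function; the global RNG state of
  the calling session is never disturbed, and identical inputs give
  bit-identical results (asserted in the tests, including byte-identical
  CLI output files).

## The synthetic-data generator

Real paired perfusion contrasts are not distributable with the package, so
tests and benchmarks run on a generator that emulates the structure SCCA
assumes: each latent factor is a standard-normal score vector shared by the
two views, loading on a sparse nonnegative unit-L2 pattern per view
(loadings uniform on $(0.5, 1]$ before normalization), with independent
Gaussian noise added. Defaults are $n = 50$ samples, $p_1 = p_2 = 500$
features, supports of 10, `signal = 3`, `noise_sd = 1`; along the true
loadings this gives a population canonical correlation of
$\mathrm{signal}^2/(\mathrm{signal}^2 + 1) = 0.9$, the scale reported in
strong pharmacological imaging studies, and a per-feature effect size
around $d \approx 0.9$. Support sizes may differ between views
(`s1`, `s2`), which is the regime where independent per-view selection of
$c_1, c_2$ earns its keep; a `spatial` mode arranges supports as contiguous
blocks for writing compact clusters into NIfTI fixtures.

What the generator does *not* emulate: spatial autocorrelation from
smoothing, physiological and scanner noise structure, inter-subject
registration error, or any drug pharmacology. Tests passing on this
generator demonstrate algorithmic correctness and calibration, not
field-strength performance on real ASL data.

```{r example}
sim <- generate_paired_views(n = 30, p1 = 60, p2 = 60, s1 = 6, s2 = 6,
                             seed = 1)
fit <- scca(sim$X1, sim$X2, c1 = 0.4, c2 = 0.4, n_components = 2)
fit
```

## Preprocessing contract for imaging input

`read_masked_set()` binarizes the mask at $> 0$ and assembles one column
per in-mask voxel in the linear index order of the mask array (R's
column-major order; fixed and documented because weight-map export depends
on it). `mean_scale()` removes each scan's mean over in-mask voxels — the
session effect; restricting to the mask avoids diluting the mean with
background zeros, and `read_masked_set(global_mean = TRUE)` is available
for whole-volume means computed before masking.
`condition_contrast()` forms per-subject active-minus-reference differences
(e.g., drug minus placebo) after mean scaling, matched on subject id.
Column standardization happens afterwards, when the contrast matrices enter
`scca()` — the model requires standardized columns, and standardizing
before differencing would distort the contrast. Upstream spatial
preprocessing (skull stripping, coregistration, normalization, smoothing,
CBF quantification) is out of scope and expected to be done with standard
imaging tools.

## Problem sizes used in the validation suite

The test suite exercises the pipeline at sizes chosen to make the
statistical assertions sharp while keeping a full run of the suite fast on
one CPU: operator oracles at $p \le 80$; dense-SVD and explicit-deflation
equivalence at $p \le 50$; support recovery and per-view selection at
$n = 50$, $p = 500$ with $k = 25$–$100$ permutations over the default 7 × 7
grid; permutation-test calibration with $m = 3$ components, $k = 199$
permutations and 200 null replicates at $n = 30$, $p = 50$; and power
screening over 20 seeds with $k = 99$. The power check deserves a note on
its regime: permuted data still admit overfit sparse correlations (about
0.95 at $n = 50$, $p = 500$ on the default grid), so a factor is detectable
only when its canonical correlation clears that floor. The screening
simulation therefore uses a strong factor (`signal = 10`, population
$q = 0.99$) and an L1 budget matched to the 10-sparse truth
($c = 0.15 \approx \sqrt{10/500}$), under which the first component absorbs
the factor and the second is pure noise. The acceptance script re-runs
selection, fitting and testing from scratch at the default study size with
$k = 100$ (selection) and $k = 199$ (significance).

## Known limitations

* Deflation is the classical rank-1 subtraction; orthogonalizing variants
  are not provided, and successive components can share features.
* Canonical vectors are multivariate weights: they should not be
  thresholded for voxel-level inference, and no multiplicity correction
  across components is applied — raw p-values are reported.
* The selection z-statistic compares against a sparse-CCA-specific null
  that is positively biased (permuted data still admit overfit sparse
  correlations, especially at loose budgets and small $n$); it is a
  *relative* criterion across the grid, not an absolute effect-size scale.
* Only two views are supported, and only the LASSO (+ nonnegativity)
  penalty; structured penalties (fused, group, total-variation) are out of
  scope.
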