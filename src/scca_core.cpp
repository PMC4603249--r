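#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::uvec;
using arma::uword;
using arma::vec;

// Soft-thresholding operator. Signed mode: sign(a) * max(|a| - delta, 0).
// Nonnegative mode: max(a - delta, 0) (negative inputs are clipped away).
static vec soft_vec(const vec& a, double delta, bool nonneg) {
  vec r(a.n_elem);
  if (nonneg) {
    for (uword i = 0; i < a.n_elem; ++i) {
      double x = a(i) - delta;
      r(i) = x > 0.0 ? x : 0.0;
    }
  } else {
    for (uword i = 0; i < a.n_elem; ++i) {
      double x = std::fabs(a(i)) - delta;
      r(i) = x > 0.0 ? (a(i) > 0.0 ? x : -x) : 0.0;
    }
  }
  return r;
}

// Projection onto {w : ||w||_2 = 1, ||w||_1 <= s} along the soft-threshold
// path: w(delta) = S(a, delta)/||S(a, delta)||_2, with delta* = 0 when the
// L1 constraint is inactive, otherwise located by bisection (||w(delta)||_1
// is non-increasing in delta).  Ties in the leading magnitudes can make
// ||w||_1 = s unattainable; then the first floor(s^2) maximal entries
// (lowest index first) are retained with equal weight.
// Returns 0 on success, 1 when no admissible direction exists.
static int l1_project_core(const vec& a, double s, bool nonneg,
                           vec& w, double& delta_out) {
  vec b = nonneg ? soft_vec(a, 0.0, true) : a;
  double mx = (b.n_elem > 0) ? arma::abs(b).max() : 0.0;
  if (!(mx > 0.0)) return 1;

  vec w0 = b / arma::norm(b, 2);
  if (arma::norm(w0, 1) <= s + 1e-12) {
    w = w0;
    delta_out = 0.0;
    return 0;
  }

  // ||w(delta)||_1 evaluated without materializing w: accumulate the L1 and
  // L2 norms of S(b, delta) in one pass.
  auto l1_of_unit = [&](double delta) {
    double s1 = 0.0, s2 = 0.0;
    for (uword i = 0; i < b.n_elem; ++i) {
      double x = nonneg ? b(i) : std::fabs(b(i));
      double t = x - delta;
      if (t > 0.0) {
        s1 += t;
        s2 += t * t;
      }
    }
    return (s2 > 0.0) ? s1 / std::sqrt(s2) : 0.0;
  };

  double lo = 0.0, hi = mx;
  for (int it = 0; it < 100; ++it) {
    double mid = 0.5 * (lo + hi);
    double l1 = l1_of_unit(mid);
    if (std::fabs(l1 - s) < 1e-12) {
      lo = hi = mid;
      break;
    }
    if (l1 > s) lo = mid; else hi = mid;
  }
  delta_out = 0.5 * (lo + hi);
  vec cur = soft_vec(b, delta_out, nonneg);
  double n2 = arma::norm(cur, 2);
  bool feasible = false;
  if (n2 > 0.0) {
    w = cur / n2;
    feasible = arma::norm(w, 1) <= s + 1e-6;
  }
  if (!feasible) {
    uvec tied = arma::find(arma::abs(b) >= mx * (1.0 - 1e-12));
    uword keep = (uword)std::max(1.0, std::floor(s * s + 1e-9));
    if (tied.n_elem > keep) tied = tied.head(keep);
    w.zeros(b.n_elem);
    for (uword j = 0; j < tied.n_elem; ++j)
      w(tied(j)) = (b(tied(j)) >= 0.0) ? 1.0 : -1.0;
    w /= arma::norm(w, 2);
    delta_out = mx;
  }
  return 0;
}

// Matrix-free products with the deflated cross-product matrix
//   Z_def = X1' X2 - sum_i d_i u_i v_i'
// (U, V hold prior canonical vectors column-wise, d the bilinear scores).
static vec zv_prod(const mat& X1, const mat& X2, const mat& U, const mat& V,
                   const vec& d, const vec& v) {
  vec r = X1.t() * (X2 * v);
  for (uword i = 0; i < d.n_elem; ++i)
    r -= d(i) * arma::dot(V.col(i), v) * U.col(i);
  return r;
}

static vec ztu_prod(const mat& X1, const mat& X2, const mat& U, const mat& V,
                    const vec& d, const vec& u) {
  vec r = X2.t() * (X1 * u);
  for (uword i = 0; i < d.n_elem; ++i)
    r -= d(i) * arma::dot(U.col(i), u) * V.col(i);
  return r;
}

// [[Rcpp::export]]
arma::vec soft_threshold_cpp(const arma::vec& a, double delta, bool nonneg) {
  return soft_vec(a, delta, nonneg);
}

// [[Rcpp::export]]
List l1_project_cpp(const arma::vec& a, double s, bool nonneg) {
  vec w;
  double delta = 0.0;
  int code = l1_project_core(a, s, nonneg, w, delta);
  if (code != 0) w.zeros(a.n_elem);
  return List::create(_["w"] = w, _["delta"] = delta,
                      _["degenerate"] = (code != 0));
}

// [[Rcpp::export]]
arma::vec deflated_product_cpp(const arma::mat& X1, const arma::mat& X2,
                               const arma::mat& U, const arma::mat& V,
                               const arma::vec& d, const arma::vec& w,
                               bool transpose) {
  return transpose ? ztu_prod(X1, X2, U, V, d, w)
                   : zv_prod(X1, X2, U, V, d, w);
}

// Rank-1 penalized matrix decomposition of the deflated cross-product
// matrix: alternating L1/L2-constrained updates of u and v.  v_start seeds
// a power iteration estimating the leading right singular direction of
// Z_def (taken elementwise-absolute in nonnegative mode).
// [[Rcpp::export]]
List scca_rank1_cpp(const arma::mat& X1, const arma::mat& X2,
                    double c1, double c2, bool nonneg,
                    int max_iter, double tol,
                    const arma::vec& v_start, int power_iter,
                    const arma::mat& U, const arma::mat& V,
                    const arma::vec& d) {
  const uword p1 = X1.n_cols, p2 = X2.n_cols;
  const double s1 = c1 * std::sqrt((double)p1);
  const double s2 = c2 * std::sqrt((double)p2);

  auto degenerate_result = [&](int iters) {
    return List::create(
        _["u"] = vec(p1, arma::fill::zeros),
        _["v"] = vec(p2, arma::fill::zeros),
        _["q_raw"] = 0.0, _["iterations"] = iters,
        _["converged"] = false, _["degenerate"] = true,
        _["objective"] = NumericVector(0));
  };

  vec v = v_start;
  double nv = arma::norm(v, 2);
  if (!(nv > 0.0)) return degenerate_result(0);
  v /= nv;
  for (int t = 0; t < power_iter; ++t) {
    vec z = ztu_prod(X1, X2, U, V, d, zv_prod(X1, X2, U, V, d, v));
    double nz = arma::norm(z, 2);
    if (!(nz > 0.0)) break;
    v = z / nz;
  }
  if (nonneg) {
    v = arma::abs(v);
  } else if (v(arma::abs(v).index_max()) < 0.0) {
    v = -v;
  }

  vec u(p1, arma::fill::zeros), u_old(p1, arma::fill::zeros), v_old = v;
  std::vector<double> objective;
  bool converged = false;
  int iter = 0;
  double delta_u = 0.0, delta_v = 0.0;

  while (iter < max_iter) {
    ++iter;
    vec a = zv_prod(X1, X2, U, V, d, v);
    vec u_new;
    double du = 0.0;
    if (l1_project_core(a, s1, nonneg, u_new, du) != 0)
      return degenerate_result(iter);

    vec b = ztu_prod(X1, X2, U, V, d, u_new);
    vec v_new;
    double dv = 0.0;
    if (l1_project_core(b, s2, nonneg, v_new, dv) != 0)
      return degenerate_result(iter);

    objective.push_back(arma::dot(b, v_new));
    delta_u = arma::abs(u_new - u_old).max();
    delta_v = arma::abs(v_new - v_old).max();
    u = u_new;
    v = v_new;
    if (iter > 1 && std::max(delta_u, delta_v) < tol) {
      converged = true;
      u_old = u;
      v_old = v;
      break;
    }
    u_old = u;
    v_old = v;
  }

  double q_raw = objective.empty() ? 0.0 : objective.back();
  return List::create(
      _["u"] = u, _["v"] = v, _["q_raw"] = q_raw,
      _["iterations"] = iter, _["converged"] = converged,
      _["degenerate"] = false,
      _["objective"] = NumericVector(objective.begin(), objective.end()));
}
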