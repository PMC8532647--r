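// Epsilon-insensitive support vector regression with an RBF kernel,
// solved by SMO (maximal violating pair) on the standard 2n-variable dual.
// Problem sizes here are tiny (one drift model per feature is fit on the
// ~12 QC injections of a batch), but the leave-one-out grid search over
// (epsilon, gamma) multiplies into hundreds of thousands of solves per
// batch, hence compiled code.
//
// Dual: min over a in R^{2n}, 0 <= a <= C, sum(s_t a_t) = 0
//   f(a) = 1/2 sum_{t,u} s_t s_u K(bt,bu) a_t a_u + sum_t (eps - s_t y_bt) a_t
// where s_t = +1 for t < n (alpha) and -1 otherwise (alpha*), bt = t mod n.
// beta = alpha - alpha*; prediction f(x) = sum_i beta_i K(x_i, x) + b.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct SvrFit {
  std::vector<double> beta;  // length m (active subset)
  double b;
};

// Solve on the subset idx of the training points. K is the full kernel
// matrix for the current gamma; y the full response vector.
SvrFit solve_svr(const std::vector<int>& idx,
                 const std::vector<double>& K, int n_full,
                 const NumericVector& y, double C, double eps,
                 int max_iter = 50000, double tol = 5e-3) {
  const int m = static_cast<int>(idx.size());
  const int N = 2 * m;
  std::vector<double> a(N, 0.0), G(N), s(N);
  for (int t = 0; t < N; ++t) {
    const int bt = t % m;
    s[t] = (t < m) ? 1.0 : -1.0;
    G[t] = eps - s[t] * y[idx[bt]];
  }
  auto Kat = [&](int bi, int bj) { return K[idx[bi] * n_full + idx[bj]]; };

  for (int iter = 0; iter < max_iter; ++iter) {
    // working set: i by maximal violation, j by second-order gain
    // (first-order selection zigzags badly when the kernel matrix is
    // near-singular and C is effectively unbounded)
    int i = -1;
    double m_up = -HUGE_VAL, m_low = HUGE_VAL;
    for (int t = 0; t < N; ++t) {
      const double g = -s[t] * G[t];
      const bool up = (s[t] > 0) ? (a[t] < C) : (a[t] > 0);
      const bool low = (s[t] > 0) ? (a[t] > 0) : (a[t] < C);
      if (up && g > m_up) { m_up = g; i = t; }
      if (low && g < m_low) m_low = g;
    }
    if (i < 0 || m_up - m_low < tol) break;
    const int bi0 = i % m;
    int j = -1;
    double best_gain = 0.0, eta_j = 1e-12;
    for (int t = 0; t < N; ++t) {
      const double g = -s[t] * G[t];
      const bool low = (s[t] > 0) ? (a[t] > 0) : (a[t] < C);
      if (!low || g >= m_up) continue;
      const double bdiff = m_up - g;
      double eta = Kat(bi0, bi0) + Kat(t % m, t % m) -
        2.0 * s[i] * s[t] * Kat(bi0, t % m);
      if (eta < 1e-12) eta = 1e-12;
      const double gain = bdiff * bdiff / eta;
      if (gain > best_gain) { best_gain = gain; j = t; eta_j = eta; }
    }
    if (j < 0) break;
    const int bi = i % m, bj = j % m;
    const double eta = eta_j;
    double delta = (m_up - (-s[j] * G[j])) / eta;
    // box constraints: a_i moves by +s_i*delta, a_j by -s_j*delta
    const double cap_i = (s[i] > 0) ? (C - a[i]) : a[i];
    const double cap_j = (s[j] > 0) ? a[j] : (C - a[j]);
    if (delta > cap_i) delta = cap_i;
    if (delta > cap_j) delta = cap_j;
    if (delta <= 0) break;
    a[i] += s[i] * delta;  // toward its cap (C if s_i>0, 0 if s_i<0)
    a[j] -= s[j] * delta;
    for (int t = 0; t < N; ++t) {
      const int bt = t % m;
      G[t] += s[t] * delta * (Kat(bt, bi) - Kat(bt, bj));
    }
  }

  SvrFit fit;
  fit.beta.assign(m, 0.0);
  for (int t = 0; t < m; ++t) fit.beta[t] = a[t] - a[t + m];
  // bias from free variables; fall back to the KKT interval midpoint
  double bsum = 0.0; int nfree = 0;
  double m_up = -HUGE_VAL, m_low = HUGE_VAL;
  for (int t = 0; t < N; ++t) {
    const double g = -s[t] * G[t];
    const bool up = (s[t] > 0) ? (a[t] < C) : (a[t] > 0);
    const bool low = (s[t] > 0) ? (a[t] > 0) : (a[t] < C);
    if (up && g > m_up) m_up = g;
    if (low && g < m_low) m_low = g;
    if (a[t] > 0 && a[t] < C) { bsum += -s[t] * G[t]; ++nfree; }
  }
  fit.b = nfree > 0 ? bsum / nfree : 0.5 * (m_up + m_low);
  return fit;
}

inline double predict_one(const std::vector<int>& idx,
                          const SvrFit& fit, const NumericVector& x,
                          double gamma, double xq) {
  double out = fit.b;
  for (size_t t = 0; t < idx.size(); ++t) {
    const double d = x[idx[t]] - xq;
    out += fit.beta[t] * std::exp(-gamma * d * d);
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
List cpp_qcsvr_select(NumericVector x, NumericVector y,
                      NumericVector eps_grid, NumericVector gamma_grid,
                      double cost) {
  const int n = x.size();
  if (y.size() != n) stop("x and y lengths differ");
  if (n < 4) stop("need >= 4 QC points");

  double best_rmse = HUGE_VAL, best_eps = NA_REAL, best_gamma = NA_REAL;
  std::vector<double> K(n * n);
  std::vector<int> all(n), loo(n - 1);
  for (int i = 0; i < n; ++i) all[i] = i;

  // gamma outer, epsilon inner, strict improvement only: ties resolve to
  // the smaller gamma, then the smaller epsilon.
  for (int gi = 0; gi < gamma_grid.size(); ++gi) {
    const double gamma = gamma_grid[gi];
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) {
        const double d = x[i] - x[j];
        K[i * n + j] = std::exp(-gamma * d * d) + (i == j ? 1e-8 : 0.0);
      }
    for (int ei = 0; ei < eps_grid.size(); ++ei) {
      const double eps = eps_grid[ei];
      double sse = 0.0;
      for (int k = 0; k < n; ++k) {
        int p = 0;
        for (int i = 0; i < n; ++i) if (i != k) loo[p++] = i;
        SvrFit fit = solve_svr(loo, K, n, y, cost, eps);
        const double r = predict_one(loo, fit, x, gamma, x[k]) - y[k];
        sse += r * r;
      }
      const double rmse = std::sqrt(sse / n);
      if (rmse < best_rmse - 1e-12) {
        best_rmse = rmse; best_eps = eps; best_gamma = gamma;
      }
    }
  }

  // final fit on all points at the selected hyperparameters
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      const double d = x[i] - x[j];
      K[i * n + j] = std::exp(-best_gamma * d * d) + (i == j ? 1e-8 : 0.0);
    }
  SvrFit fit = solve_svr(all, K, n, y, cost, best_eps);

  return List::create(_["epsilon"] = best_eps, _["gamma"] = best_gamma,
                      _["loo_rmse"] = best_rmse,
                      _["beta"] = NumericVector(fit.beta.begin(), fit.beta.end()),
                      _["b"] = fit.b);
}

// [[Rcpp::export]]
NumericVector cpp_svr_predict(NumericVector x_train, NumericVector beta,
                              double b, double gamma, NumericVector x_new) {
  const int n = x_train.size(), m = x_new.size();
  if (beta.size() != n) stop("beta length mismatch");
  NumericVector out(m);
  for (int q = 0; q < m; ++q) {
    double acc = b;
    for (int i = 0; i < n; ++i) {
      const double d = x_train[i] - x_new[q];
      acc += beta[i] * std::exp(-gamma * d * d);
    }
    out[q] = acc;
  }
  return out;
}
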