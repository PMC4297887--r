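// Soft-margin SVM trained by sequential minimal optimisation (SMO),
// plus a leave-one-out cross-validation driver with per-fold
// standardization and a polynomial kernel K(x, y) = (x'y + c)^d.
//
// The solver is a deterministic variant of Platt's SMO: the second index
// of each working pair is chosen by the max-|E1 - E2| heuristic with an
// exhaustive deterministic fallback, so identical inputs always give
// identical models. Cohort sizes here are tiny (n <= ~100), so the full
// kernel matrix and error cache are kept dense.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct SmoState {
  std::vector<double> alpha, E;
  double b;
  long long iter;
  const NumericMatrix& K;
  const std::vector<int>& y;
  double C, tol, eps;
  long long maxit;

  SmoState(const NumericMatrix& K_, const std::vector<int>& y_, double C_,
           double tol_, long long maxit_)
      : alpha(K_.nrow(), 0.0), E(K_.nrow()), b(0.0), iter(0), K(K_), y(y_),
        C(C_), tol(tol_), eps(1e-3), maxit(maxit_) {
    for (int i = 0; i < K.nrow(); ++i) E[i] = -static_cast<double>(y[i]);
  }

  // joint optimisation of the pair (i1, i2); returns true on progress
  bool take_step(int i1, int i2) {
    if (i1 == i2) return false;
    const double a1 = alpha[i1], a2 = alpha[i2];
    const int y1 = y[i1], y2 = y[i2];
    const double E1 = E[i1], E2 = E[i2];
    const double s = y1 * y2;
    double L, H;
    if (y1 != y2) {
      L = std::max(0.0, a2 - a1);
      H = std::min(C, C + a2 - a1);
    } else {
      L = std::max(0.0, a1 + a2 - C);
      H = std::min(C, a1 + a2);
    }
    if (L >= H) return false;
    const double k11 = K(i1, i1), k12 = K(i1, i2), k22 = K(i2, i2);
    const double eta = k11 + k22 - 2.0 * k12;
    double a2new;
    if (eta > 0) {
      a2new = a2 + y2 * (E1 - E2) / eta;
      if (a2new < L) a2new = L;
      else if (a2new > H) a2new = H;
    } else {
      // degenerate curvature: evaluate the objective at both clip ends
      const double f1 = y1 * (E1 + b) - a1 * k11 - s * a2 * k12;
      const double f2 = y2 * (E2 + b) - s * a1 * k12 - a2 * k22;
      const double L1 = a1 + s * (a2 - L), H1 = a1 + s * (a2 - H);
      const double psiL = L1 * f1 + L * f2 + 0.5 * L1 * L1 * k11 +
                          0.5 * L * L * k22 + s * L * L1 * k12;
      const double psiH = H1 * f1 + H * f2 + 0.5 * H1 * H1 * k11 +
                          0.5 * H * H * k22 + s * H * H1 * k12;
      if (psiL < psiH - eps) a2new = L;
      else if (psiL > psiH + eps) a2new = H;
      else a2new = a2;
    }
    if (std::fabs(a2new - a2) < eps * (a2new + a2 + eps)) return false;
    double a1new = a1 + s * (a2 - a2new);
    if (a1new < 0) { a2new += s * a1new; a1new = 0; }
    else if (a1new > C) { a2new += s * (a1new - C); a1new = C; }

    const double d1 = y1 * (a1new - a1), d2 = y2 * (a2new - a2);
    const double b1 = b - E1 - d1 * k11 - d2 * k12;
    const double b2 = b - E2 - d1 * k12 - d2 * k22;
    double bnew;
    const bool in1 = a1new > 0 && a1new < C, in2 = a2new > 0 && a2new < C;
    if (in1) bnew = b1;
    else if (in2) bnew = b2;
    else bnew = 0.5 * (b1 + b2);
    const double db = bnew - b;
    b = bnew;
    const int n = static_cast<int>(alpha.size());
    for (int k = 0; k < n; ++k) E[k] += d1 * K(i1, k) + d2 * K(i2, k) + db;
    alpha[i1] = a1new;
    alpha[i2] = a2new;
    ++iter;
    return true;
  }

  int examine(int i2) {
    const double E2 = E[i2];
    const double r2 = E2 * y[i2];
    const double a2 = alpha[i2];
    if (!((r2 < -tol && a2 < C) || (r2 > tol && a2 > 0))) return 0;
    const int n = static_cast<int>(alpha.size());
    int best = -1;
    double gap = -1.0;
    for (int j = 0; j < n; ++j) {
      if (j == i2) continue;
      const double g = std::fabs(E2 - E[j]);
      if (g > gap) { gap = g; best = j; }
    }
    if (best >= 0 && take_step(best, i2)) return 1;
    for (int j = 0; j < n; ++j)
      if (j != i2 && take_step(j, i2)) return 1;
    return 0;
  }

  bool solve() {
    bool examine_all = true;
    while (iter < maxit) {
      int changed = 0;
      const int n = static_cast<int>(alpha.size());
      for (int i = 0; i < n && iter < maxit; ++i)
        if (examine_all || (alpha[i] > 0 && alpha[i] < C)) changed += examine(i);
      if (examine_all) {
        if (changed == 0) return true;  // KKT satisfied everywhere
        examine_all = false;
      } else if (changed == 0) {
        examine_all = true;
      }
    }
    return false;  // iteration budget exhausted
  }
};

inline double poly_kernel(const double* x, const double* z, int p,
                          double coef0, int degree) {
  double dot = 0.0;
  for (int k = 0; k < p; ++k) dot += x[k] * z[k];
  return std::pow(dot + coef0, degree);
}

}  // namespace

// [[Rcpp::export]]
List smo_solve_cpp(NumericMatrix K, IntegerVector y, double C, double tol,
                   double max_iter) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n) stop("kernel/label dimension mismatch");
  std::vector<int> yy(y.begin(), y.end());
  SmoState st(K, yy, C, tol, static_cast<long long>(max_iter));
  const bool converged = st.solve();
  return List::create(_["alpha"] = NumericVector(st.alpha.begin(), st.alpha.end()),
                      _["b"] = st.b,
                      _["iterations"] = static_cast<double>(st.iter),
                      _["converged"] = converged);
}

// Leave-one-out CV of the polynomial-kernel SVM on X (n x p), y in
// {-1, +1}. For each fold the held-in rows are standardized (mean 0,
// unit variance; zero-variance columns get scale 1) and the same
// transform is applied to the held-out point. A decision value of
// exactly 0 is classified as non-converter (-1).
// [[Rcpp::export]]
List loo_cv_cpp(NumericMatrix X, IntegerVector y, int degree, double coef0,
                double C, bool standardize, double tol, double max_iter) {
  const int n = X.nrow(), p = X.ncol();
  if (n < 4) stop("LOO-CV needs >= 4 patients");
  int tp = 0, fp = 0, tn = 0, fn = 0, nonconv = 0;
  const int m = n - 1;
  std::vector<double> Z(static_cast<size_t>(m) * p), zh(p), mu(p), sd(p);
  std::vector<int> ytr(m);

  for (int hold = 0; hold < n; ++hold) {
    int cpos = 0, cneg = 0;
    for (int i = 0, r = 0; i < n; ++i) {
      if (i == hold) continue;
      ytr[r] = y[i];
      if (y[i] > 0) ++cpos; else ++cneg;
      for (int k = 0; k < p; ++k) Z[static_cast<size_t>(r) * p + k] = X(i, k);
      ++r;
    }
    if (cpos == 0 || cneg == 0)
      stop("a training fold lost an entire class; need >= 2 per class");

    if (standardize) {
      for (int k = 0; k < p; ++k) {
        double s = 0.0;
        for (int r = 0; r < m; ++r) s += Z[static_cast<size_t>(r) * p + k];
        mu[k] = s / m;
        double v = 0.0;
        for (int r = 0; r < m; ++r) {
          const double d = Z[static_cast<size_t>(r) * p + k] - mu[k];
          v += d * d;
        }
        sd[k] = m > 1 ? std::sqrt(v / (m - 1)) : 1.0;
        if (sd[k] <= 0.0) sd[k] = 1.0;
        for (int r = 0; r < m; ++r)
          Z[static_cast<size_t>(r) * p + k] =
              (Z[static_cast<size_t>(r) * p + k] - mu[k]) / sd[k];
        zh[k] = (X(hold, k) - mu[k]) / sd[k];
      }
    } else {
      for (int k = 0; k < p; ++k) zh[k] = X(hold, k);
    }

    NumericMatrix K(m, m);
    for (int i = 0; i < m; ++i)
      for (int j = i; j < m; ++j) {
        const double v = poly_kernel(&Z[static_cast<size_t>(i) * p],
                                     &Z[static_cast<size_t>(j) * p], p, coef0,
                                     degree);
        K(i, j) = v;
        K(j, i) = v;
      }

    SmoState st(K, ytr, C, tol, static_cast<long long>(max_iter));
    if (!st.solve()) ++nonconv;

    double f = st.b;
    for (int i = 0; i < m; ++i)
      if (st.alpha[i] > 0)
        f += st.alpha[i] * ytr[i] *
             poly_kernel(&Z[static_cast<size_t>(i) * p], zh.data(), p, coef0,
                         degree);
    const int pred = f > 0 ? 1 : -1;
    if (y[hold] > 0) { if (pred > 0) ++tp; else ++fn; }
    else             { if (pred < 0) ++tn; else ++fp; }
  }
  return List::create(_["tp"] = tp, _["fp"] = fp, _["tn"] = tn, _["fn"] = fn,
                      _["n_nonconverged"] = nonconv);
}
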