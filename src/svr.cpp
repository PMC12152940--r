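#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// epsilon-insensitive support vector regression with an RBF kernel and
// PER-SAMPLE box constraints C_i, solved by SMO with maximal-violating-pair
// working-set selection. Uniform C_i reproduces the standard epsilon-SVR, so
// the weighted and unweighted regressors share one solver.
//
// Dual (a has 2n entries: a[0..n) = alpha, a[n..2n) = alpha*):
//   min 1/2 (alpha-alpha*)' K (alpha-alpha*) + eps*sum(a) - y'(alpha-alpha*)
//   s.t. sum(alpha - alpha*) = 0,  0 <= a_t <= C_{t mod n}

// [[Rcpp::export(name = ".rbf_kernel_cpp")]]
NumericMatrix rbf_kernel_cpp(NumericMatrix A, NumericMatrix B, double gamma) {
  int na = A.nrow(), nb = B.nrow(), p = A.ncol();
  NumericMatrix K(na, nb);
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < nb; ++j) {
      double d = 0.0;
      for (int f = 0; f < p; ++f) {
        double t = A(i, f) - B(j, f);
        d += t * t;
      }
      K(i, j) = std::exp(-gamma * d);
    }
  return K;
}

// [[Rcpp::export(name = ".svr_smo_cpp")]]
List svr_smo_cpp(NumericMatrix K, NumericVector y, NumericVector C,
                 double eps_tube, double tol, int max_iter) {
  int n = y.size();
  if (K.nrow() != n || K.ncol() != n) stop("kernel matrix dimension mismatch");
  std::vector<double> a(2 * n, 0.0), G(2 * n), P(2 * n);
  std::vector<int> Z(2 * n); // +1 for alpha block, -1 for alpha* block
  for (int i = 0; i < n; ++i) {
    P[i] = eps_tube - y[i];     Z[i] = 1;
    P[n + i] = eps_tube + y[i]; Z[n + i] = -1;
    G[i] = P[i]; G[n + i] = P[n + i];
  }
  auto Cof = [&](int t) { return C[t % n]; };

  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // working set: i maximizes -z*G over "up" set, j minimizes over "down" set
    double gmax = -HUGE_VAL, gmin = HUGE_VAL;
    int i = -1, j = -1;
    for (int t = 0; t < 2 * n; ++t) {
      bool up = (Z[t] > 0) ? (a[t] < Cof(t)) : (a[t] > 0);
      bool dn = (Z[t] > 0) ? (a[t] > 0) : (a[t] < Cof(t));
      double v = -Z[t] * G[t];
      if (up && v > gmax) { gmax = v; i = t; }
      if (dn && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < tol) break;

    int ri = i % n, rj = j % n;
    double kii = K(ri, ri), kjj = K(rj, rj), kij = K(ri, rj);
    double old_ai = a[i], old_aj = a[j];
    if (Z[i] != Z[j]) {
      double quad = kii + kjj + 2.0 * kij;
      if (quad <= 0) quad = 1e-12;
      double delta = (-G[i] - G[j]) / quad;
      double diff = a[i] - a[j];
      a[i] += delta; a[j] += delta;
      if (diff > 0 && a[j] < 0) { a[j] = 0; a[i] = diff; }
      else if (diff <= 0 && a[i] < 0) { a[i] = 0; a[j] = -diff; }
      if (diff > Cof(i) - Cof(j) && a[i] > Cof(i)) { a[i] = Cof(i); a[j] = Cof(i) - diff; }
      else if (diff <= Cof(i) - Cof(j) && a[j] > Cof(j)) { a[j] = Cof(j); a[i] = Cof(j) + diff; }
    } else {
      double quad = kii + kjj - 2.0 * kij;
      if (quad <= 0) quad = 1e-12;
      double delta = (G[i] - G[j]) / quad;
      double sum = a[i] + a[j];
      a[i] -= delta; a[j] += delta;
      if (sum > Cof(i) && a[i] > Cof(i)) { a[i] = Cof(i); a[j] = sum - Cof(i); }
      else if (sum <= Cof(i) && a[j] < 0) { a[j] = 0; a[i] = sum; }
      if (sum > Cof(j) && a[j] > Cof(j)) { a[j] = Cof(j); a[i] = sum - Cof(j); }
      else if (sum <= Cof(j) && a[i] < 0) { a[i] = 0; a[j] = sum; }
    }
    double di = a[i] - old_ai, dj = a[j] - old_aj;
    if (di == 0.0 && dj == 0.0) break;
    for (int t = 0; t < 2 * n; ++t) {
      int rt = t % n;
      G[t] += Z[t] * (Z[i] * K(rt, ri) * di + Z[j] * K(rt, rj) * dj);
    }
  }

  // intercept: b = -z_t * G_t for any free variable (0 < a_t < C_t);
  // averaged over all free variables, midpoint of the KKT bounds otherwise
  double bsum = 0.0; int nfree = 0;
  double vmax = -HUGE_VAL, vmin = HUGE_VAL;
  for (int t = 0; t < 2 * n; ++t) {
    double v = -Z[t] * G[t];
    bool up = (Z[t] > 0) ? (a[t] < Cof(t)) : (a[t] > 0);
    bool dn = (Z[t] > 0) ? (a[t] > 0) : (a[t] < Cof(t));
    if (a[t] > 0 && a[t] < Cof(t)) { bsum += v; ++nfree; }
    if (up) vmax = std::max(vmax, v);
    if (dn) vmin = std::min(vmin, v);
  }
  double b = (nfree > 0) ? bsum / nfree : (vmax + vmin) / 2.0;

  NumericVector beta(n);
  for (int i2 = 0; i2 < n; ++i2) beta[i2] = a[i2] - a[n + i2];
  return List::create(_["beta"] = beta, _["b"] = b,
                      _["iterations"] = iter,
                      _["converged"] = iter < max_iter);
}
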