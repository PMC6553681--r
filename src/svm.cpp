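// Dual coordinate descent for the L1-loss linear SVM (Hsieh et al. style):
// maximise the dual with alpha_i in [0, C], w = sum alpha_i y_i x_i.
// The caller augments X with a constant column so the bias is regularized
// into w. Deterministic given the integer seed.

#include <Rcpp.h>
#include <random>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".svm_dcd")]]
NumericVector svm_dcd(NumericMatrix X, NumericVector y, double C, int seed,
                      int max_pass, double tol) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> w(p, 0.0), alpha(n, 0.0), Qii(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < p; ++j) s += X(i, j) * X(i, j);
    Qii[i] = s;
  }
  std::mt19937 rng((uint32_t)seed);
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  for (int pass = 0; pass < max_pass; ++pass) {
    for (int i = n - 1; i > 0; --i) {
      std::uniform_int_distribution<int> d(0, i);
      std::swap(perm[i], perm[d(rng)]);
    }
    double worst = 0.0;
    for (int k = 0; k < n; ++k) {
      int i = perm[k];
      double G = 0.0;
      for (int j = 0; j < p; ++j) G += w[j] * X(i, j);
      G = y[i] * G - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0 && G > 0.0) PG = 0.0;
      else if (alpha[i] >= C && G < 0.0) PG = 0.0;
      if (std::abs(PG) > worst) worst = std::abs(PG);
      if (std::abs(PG) > 1e-12 && Qii[i] > 0.0) {
        double a = alpha[i] - G / Qii[i];
        if (a < 0.0) a = 0.0;
        if (a > C) a = C;
        double delta = (a - alpha[i]) * y[i];
        if (delta != 0.0) {
          for (int j = 0; j < p; ++j) w[j] += delta * X(i, j);
          alpha[i] = a;
        }
      }
    }
    if (worst < tol) break;
  }
  return NumericVector(w.begin(), w.end());
}
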