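#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// The convolution matrix is (N*P) x d, stored position-fastest: the value
// of kernel k at position p of record i sits at p + i*P + k*N*P (0-based).
// Kernel k only has Pm[k] = L - m_k + 1 valid positions; entries beyond
// that come from windows running past the true input and are ignored.
// act selects the convolution activation applied on the fly:
// 0 = ReLU, 1 = sigmoid.

static inline double activate1(double x, int act) {
  return act == 0 ? (x > 0.0 ? x : 0.0) : 1.0 / (1.0 + std::exp(-x));
}

// Activation + global max/average pooling per (record, kernel) group.
// Returns max (N x d), 0-based argmax (N x d) and the mean over the valid
// positions (N x d), all on the activated values.
// [[Rcpp::export(name = ".poolForward")]]
List poolForward(NumericVector X, int N, int P, IntegerVector Pm, int act) {
  const int d = Pm.size();
  NumericMatrix ymax(N, d), yavg(N, d);
  IntegerMatrix amax(N, d);
  const double* x = X.begin();
  for (int k = 0; k < d; ++k) {
    const int pk = Pm[k];
    for (int i = 0; i < N; ++i) {
      const double* col = x + ((size_t)k * N + i) * P;
      double m = activate1(col[0], act);
      int am = 0;
      double s = m;
      for (int p = 1; p < pk; ++p) {
        const double v = activate1(col[p], act);
        s += v;
        if (v > m) { m = v; am = p; }
      }
      ymax(i, k) = m;
      amax(i, k) = am;
      yavg(i, k) = s / pk;
    }
  }
  return List::create(_["max"] = ymax, _["argmax"] = amax,
                      _["avg"] = yavg);
}

// Gradient through pooling and the convolution activation in one pass:
// spreads the average-pool gradient over the valid positions, adds the
// max-pool gradient at the argmax, and multiplies by the activation
// derivative computed from the pre-activation X. Invalid positions get
// zero gradient.
// [[Rcpp::export(name = ".poolBackward")]]
NumericVector poolBackward(NumericVector X, NumericMatrix dymax,
                           NumericMatrix dyavg, IntegerMatrix amax,
                           int N, int P, IntegerVector Pm, int act) {
  const int d = Pm.size();
  NumericVector dA((size_t)N * P * d);   // zero-initialized
  const double* xp = X.begin();
  double* out = dA.begin();
  for (int k = 0; k < d; ++k) {
    const int pk = Pm[k];
    for (int i = 0; i < N; ++i) {
      const size_t base = ((size_t)k * N + i) * P;
      const double g = dyavg(i, k) / pk;
      const int am = amax(i, k);
      const double gm = dymax(i, k);
      for (int p = 0; p < pk; ++p) {
        double v = g + (p == am ? gm : 0.0);
        if (act == 0) {
          if (xp[base + p] <= 0.0) v = 0.0;
        } else {
          const double a = 1.0 / (1.0 + std::exp(-xp[base + p]));
          v *= a * (1.0 - a);
        }
        out[base + p] = v;
      }
    }
  }
  return dA;
}
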