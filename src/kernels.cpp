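#include <Rcpp.h>
using namespace Rcpp;

// Per-channel exponential-moving-average scan: s_t = a_c s_{t-1} + (1 - a_c) u_t.
// The decay a_c is in (0, 1); values near 1 give near-global receptive fields.
// [[Rcpp::export]]
NumericMatrix ema_scan(NumericMatrix u, NumericVector a) {
  const int n = u.nrow(), d = u.ncol();
  if (a.size() != d) stop("decay vector length must equal the number of channels");
  NumericMatrix s(n, d);
  for (int c = 0; c < d; ++c) {
    const double ac = a[c];
    double prev = 0.0;
    for (int t = 0; t < n; ++t) {
      prev = ac * prev + (1.0 - ac) * u(t, c);
      s(t, c) = prev;
    }
  }
  return s;
}

// Reverse-mode gradients of ema_scan. g is dL/ds; returns dL/du and dL/da.
// Adjoint recurrence: gbar_t = g_t + a gbar_{t+1};
//   dL/du_t = (1 - a) gbar_t;  dL/da = sum_t gbar_t (s_{t-1} - u_t).
// [[Rcpp::export]]
List ema_scan_grad(NumericMatrix u, NumericVector a, NumericMatrix s,
                   NumericMatrix g) {
  const int n = u.nrow(), d = u.ncol();
  NumericMatrix gu(n, d);
  NumericVector ga(d);
  for (int c = 0; c < d; ++c) {
    const double ac = a[c];
    double acc = 0.0, gsum = 0.0;
    for (int t = n - 1; t >= 0; --t) {
      acc = g(t, c) + ac * acc;
      const double sprev = (t > 0) ? s(t - 1, c) : 0.0;
      gu(t, c) = (1.0 - ac) * acc;
      gsum += acc * (sprev - u(t, c));
    }
    ga[c] = gsum;
  }
  return List::create(_["gu"] = gu, _["ga"] = ga);
}

// Transition-penalised decoding: minimise
//   -sum_i log p[i, S_i] + lambda * #{i : S_i != S_{i+1}}
// by forward dynamic programming with backtracking.  logp holds log
// probabilities (already clamped).  Ties broken toward the lowest state
// index.  Returns 1-based state indices.
// [[Rcpp::export]]
IntegerVector smooth_dp(NumericMatrix logp, double lambda) {
  const int n = logp.nrow(), J = logp.ncol();
  if (n == 0) return IntegerVector(0);
  std::vector<double> D(J), Dn(J);
  IntegerMatrix prev(n, J);
  for (int k = 0; k < J; ++k) D[k] = -logp(0, k);
  for (int i = 1; i < n; ++i) {
    int jstar = 0;
    double m = D[0];
    for (int j = 1; j < J; ++j)
      if (D[j] < m) { m = D[j]; jstar = j; }
    for (int k = 0; k < J; ++k) {
      const double stay = D[k], sw = m + lambda;
      if (sw < stay || (sw == stay && jstar < k)) {
        Dn[k] = sw - logp(i, k);
        prev(i, k) = jstar;
      } else {
        Dn[k] = stay - logp(i, k);
        prev(i, k) = k;
      }
    }
    std::swap(D, Dn);
  }
  int kstar = 0;
  double m = D[0];
  for (int k = 1; k < J; ++k)
    if (D[k] < m) { m = D[k]; kstar = k; }
  IntegerVector out(n);
  out[n - 1] = kstar;
  for (int i = n - 1; i > 0; --i) out[i - 1] = prev(i, out[i]);
  for (int i = 0; i < n; ++i) out[i] += 1;
  return out;
}
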