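#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward recursions for one chain segment.
//
// logB:  T x K expected log observation densities (sub-normalized values,
//        as produced by expectations under a Gaussian-Wishart posterior,
//        are fine: the scaling constants absorb them).
// logA:  K x K expected log transition weights.
// logpi: K expected log initial-state weights.
//
// Per-time normalization keeps the recursions stable for T up to 1e6;
// the log normalizers are accumulated and returned as logZ.
// [[Rcpp::export]]
List forward_backward_cpp(NumericMatrix logB, NumericMatrix logA,
                          NumericVector logpi) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix b(T, K);
  NumericVector bshift(T);
  for (int t = 0; t < T; ++t) {
    double m = logB(t, 0);
    for (int k = 1; k < K; ++k) if (logB(t, k) > m) m = logB(t, k);
    bshift[t] = m;
    for (int k = 0; k < K; ++k) b(t, k) = std::exp(logB(t, k) - m);
  }
  NumericMatrix A(K, K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) A(i, j) = std::exp(logA(i, j));
  NumericVector pi(K);
  for (int k = 0; k < K; ++k) pi[k] = std::exp(logpi[k]);

  NumericMatrix alpha(T, K), beta(T, K);
  NumericVector c(T);
  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * b(0, k); s += alpha(0, k); }
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int j = 0; j < K; ++j) {
      double a = 0.0;
      for (int i = 0; i < K; ++i) a += alpha(t - 1, i) * A(i, j);
      a *= b(t, j);
      alpha(t, j) = a;
      s += a;
    }
    c[t] = s;
    for (int j = 0; j < K; ++j) alpha(t, j) /= s;
  }
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += A(i, j) * b(t + 1, j) * beta(t + 1, j);
      beta(t, i) = a / c[t + 1];
    }
  }
  NumericMatrix gamma(T, K), xi(K, K);
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }
  for (int t = 1; t < T; ++t)
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j)
        xi(i, j) += alpha(t - 1, i) * A(i, j) * b(t, j) * beta(t, j) / c[t];

  double logZ = 0.0;
  for (int t = 0; t < T; ++t) logZ += std::log(c[t]) + bshift[t];
  return List::create(_["gamma"] = gamma, _["xi_sum"] = xi, _["logZ"] = logZ);
}

// Log-domain Viterbi for one chain segment. Ties break toward the lowest
// state index (strict > when scanning in increasing index order).
// Returns 1-based states.
// [[Rcpp::export]]
IntegerVector viterbi_cpp(NumericMatrix logB, NumericMatrix logA,
                          NumericVector logpi) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k) delta(0, k) = logpi[k] + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = delta(t - 1, 0) + logA(0, j);
      int arg = 0;
      for (int i = 1; i < K; ++i) {
        double v = delta(t - 1, i) + logA(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + logB(t, j);
      psi(t, j) = arg;
    }
  }
  IntegerVector path(T);
  double best = delta(T - 1, 0);
  int arg = 0;
  for (int k = 1; k < K; ++k) if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg + 1;
  for (int t = T - 1; t > 0; --t) { arg = psi(t, arg); path[t - 1] = arg + 1; }
  return path;
}

// Direct-form-II-transposed IIR filter with initial state zi
// (a[0] assumed 1 after normalization on the R side).
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  const int n = b.size();           // == a.size(), padded on the R side
  const int T = x.size();
  std::vector<double> z(zi.begin(), zi.end());
  z.resize(n - 1, 0.0);
  NumericVector y(T);
  for (int t = 0; t < T; ++t) {
    double yt = b[0] * x[t] + z[0];
    for (int i = 0; i < n - 2; ++i)
      z[i] = b[i + 1] * x[t] + z[i + 1] - a[i + 1] * yt;
    z[n - 2] = b[n - 1] * x[t] - a[n - 1] * yt;
    y[t] = yt;
  }
  return y;
}
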