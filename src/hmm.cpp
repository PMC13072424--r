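#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Scaled forward-backward for one observation sequence.
// B: T x K emission likelihoods (linear scale), A: K x K row-stochastic
// transitions, pi: K initial probabilities. Returns the total
// log-likelihood, posterior state marginals gamma (T x K, rows sum to 1)
// and the summed transition posteriors xisum (K x K).
// Internally time slices are contiguous K-vectors for cache efficiency.
// [[Rcpp::export]]
List fb_cpp(NumericMatrix B, NumericMatrix A, NumericVector pi) {
  const int T = B.nrow(), K = B.ncol();
  std::vector<double> Bt(static_cast<size_t>(T) * K);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k) Bt[static_cast<size_t>(t) * K + k] = B(t, k);
  const double *Ap = A.begin();  // column-major: A(j,k) = Ap[j + k*K]
  std::vector<double> alpha(static_cast<size_t>(T) * K),
      beta(static_cast<size_t>(T) * K);
  std::vector<double> c(T);
  double s = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha[k] = pi[k] * Bt[k];
    s += alpha[k];
  }
  if (s <= 0.0) stop("zero forward probability at bin 1");
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha[k] /= s;
  for (int t = 1; t < T; ++t) {
    const double *ap = &alpha[static_cast<size_t>(t - 1) * K];
    const double *bt = &Bt[static_cast<size_t>(t) * K];
    double *an = &alpha[static_cast<size_t>(t) * K];
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      const double *acol = Ap + static_cast<size_t>(k) * K;
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += ap[j] * acol[j];
      a *= bt[k];
      an[k] = a;
      s += a;
    }
    if (s <= 0.0) stop("zero forward probability at bin %d", t + 1);
    c[t] = s;
    const double inv = 1.0 / s;
    for (int k = 0; k < K; ++k) an[k] *= inv;
  }
  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(c[t]);
  for (int k = 0; k < K; ++k) beta[static_cast<size_t>(T - 1) * K + k] = 1.0;
  std::vector<double> bb(K);
  NumericMatrix xisum(K, K);
  double *xp = xisum.begin();
  for (int t = T - 2; t >= 0; --t) {
    const double *bn = &beta[static_cast<size_t>(t + 1) * K];
    const double *bt = &Bt[static_cast<size_t>(t + 1) * K];
    const double *ap = &alpha[static_cast<size_t>(t) * K];
    double *bc = &beta[static_cast<size_t>(t) * K];
    const double inv = 1.0 / c[t + 1];
    for (int k = 0; k < K; ++k) bb[k] = bt[k] * bn[k] * inv;
    for (int j = 0; j < K; ++j) {
      double b = 0.0;
      for (int k = 0; k < K; ++k) b += Ap[j + static_cast<size_t>(k) * K] * bb[k];
      bc[j] = b;
      const double aj = ap[j];
      if (aj != 0.0)
        for (int k = 0; k < K; ++k)
          xp[j + static_cast<size_t>(k) * K] +=
              aj * Ap[j + static_cast<size_t>(k) * K] * bb[k];
    }
  }
  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t) {
    const double *ap = &alpha[static_cast<size_t>(t) * K];
    const double *bp = &beta[static_cast<size_t>(t) * K];
    double g = 0.0;
    for (int k = 0; k < K; ++k) g += ap[k] * bp[k];
    for (int k = 0; k < K; ++k) gamma(t, k) = ap[k] * bp[k] / g;
  }
  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xisum"] = xisum);
}

// Viterbi path in log space. logB: T x K, logA: K x K, logpi: K.
// Returns 1-based state indices.
// [[Rcpp::export]]
IntegerVector viterbi_cpp(NumericMatrix logB, NumericMatrix logA,
                          NumericVector logpi) {
  const int T = logB.nrow(), K = logB.ncol();
  std::vector<double> prev(K), cur(K);
  std::vector<int> psi(static_cast<size_t>(T) * K);
  const double *Ap = logA.begin();
  for (int k = 0; k < K; ++k) prev[k] = logpi[k] + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf;
      int arg = 0;
      const double *acol = Ap + static_cast<size_t>(k) * K;
      for (int j = 0; j < K; ++j) {
        const double v = prev[j] + acol[j];
        if (v > best) { best = v; arg = j; }
      }
      cur[k] = best + logB(t, k);
      psi[static_cast<size_t>(t) * K + k] = arg;
    }
    std::swap(prev, cur);
  }
  IntegerVector path(T);
  double best = R_NegInf;
  int arg = 0;
  for (int k = 0; k < K; ++k) if (prev[k] > best) { best = prev[k]; arg = k; }
  path[T - 1] = arg + 1;
  for (int t = T - 1; t > 0; --t) {
    arg = psi[static_cast<size_t>(t) * K + arg];
    path[t - 1] = arg + 1;
  }
  return path;
}
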