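#include <Rcpp.h>
using namespace Rcpp;

// Sparse-edge HMM dynamic programming in log space. States are 1-based on
// the R side; edges carry finite log transition probabilities (zero-probability
// transitions are simply absent). logemit is n_states x L and already encodes
// positional constraint masking as -Inf. end_ok marks states a path may end in
// (loop states only, so decoded helices are always complete and loop-flanked).

static inline double logadd(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  if (a < b) std::swap(a, b);
  return a + log1p(exp(b - a));
}

// [[Rcpp::export]]
List dp_viterbi(NumericVector logstart, IntegerVector efrom, IntegerVector eto,
                NumericVector elogp, NumericMatrix logemit,
                LogicalVector end_ok) {
  const int n = logemit.nrow(), L = logemit.ncol(), ne = efrom.size();
  NumericMatrix delta(n, L);
  IntegerMatrix psi(n, L);
  for (int j = 0; j < n; ++j) {
    delta(j, 0) = logstart[j] + logemit(j, 0);
    psi(j, 0) = -1;
  }
  std::vector<double> best(n);
  std::vector<int> arg(n);
  for (int t = 1; t < L; ++t) {
    std::fill(best.begin(), best.end(), R_NegInf);
    std::fill(arg.begin(), arg.end(), -1);
    // edges are supplied sorted by source state; strict '>' keeps the
    // lexicographically smallest predecessor on ties (deterministic)
    for (int e = 0; e < ne; ++e) {
      const int i = efrom[e] - 1, j = eto[e] - 1;
      const double cand = delta(i, t - 1) + elogp[e];
      if (cand > best[j]) { best[j] = cand; arg[j] = i; }
    }
    for (int j = 0; j < n; ++j) {
      delta(j, t) = (best[j] == R_NegInf) ? R_NegInf : best[j] + logemit(j, t);
      psi(j, t) = arg[j];
    }
  }
  double bestlp = R_NegInf;
  int bestj = -1;
  for (int j = 0; j < n; ++j) {
    if (end_ok[j] && delta(j, L - 1) > bestlp) { bestlp = delta(j, L - 1); bestj = j; }
  }
  if (bestj < 0 || bestlp == R_NegInf) {
    return List::create(_["logprob"] = R_NegInf,
                        _["path"] = IntegerVector(0));
  }
  IntegerVector path(L);
  int j = bestj;
  for (int t = L - 1; t >= 0; --t) {
    path[t] = j + 1;
    j = psi(j, t);
  }
  return List::create(_["logprob"] = bestlp, _["path"] = path);
}

// [[Rcpp::export]]
List dp_forward_backward(NumericVector logstart, IntegerVector efrom,
                         IntegerVector eto, NumericVector elogp,
                         NumericMatrix logemit, LogicalVector end_ok) {
  const int n = logemit.nrow(), L = logemit.ncol(), ne = efrom.size();
  NumericMatrix alpha(n, L), beta(n, L);
  for (int j = 0; j < n; ++j) alpha(j, 0) = logstart[j] + logemit(j, 0);
  std::vector<double> acc(n);
  for (int t = 1; t < L; ++t) {
    std::fill(acc.begin(), acc.end(), R_NegInf);
    for (int e = 0; e < ne; ++e) {
      const int i = efrom[e] - 1, j = eto[e] - 1;
      acc[j] = logadd(acc[j], alpha(i, t - 1) + elogp[e]);
    }
    for (int j = 0; j < n; ++j)
      alpha(j, t) = (acc[j] == R_NegInf) ? R_NegInf : acc[j] + logemit(j, t);
  }
  for (int j = 0; j < n; ++j) beta(j, L - 1) = end_ok[j] ? 0.0 : R_NegInf;
  for (int t = L - 2; t >= 0; --t) {
    std::fill(acc.begin(), acc.end(), R_NegInf);
    for (int e = 0; e < ne; ++e) {
      const int i = efrom[e] - 1, j = eto[e] - 1;
      acc[i] = logadd(acc[i], elogp[e] + logemit(j, t + 1) + beta(j, t + 1));
    }
    for (int i = 0; i < n; ++i) beta(i, t) = acc[i];
  }
  double loglik = R_NegInf;
  for (int j = 0; j < n; ++j)
    if (end_ok[j]) loglik = logadd(loglik, alpha(j, L - 1));
  NumericMatrix post(n, L);
  if (loglik != R_NegInf) {
    for (int t = 0; t < L; ++t) {
      double s = 0.0;
      for (int j = 0; j < n; ++j) {
        const double g = alpha(j, t) + beta(j, t) - loglik;
        post(j, t) = (g == R_NegInf) ? 0.0 : exp(g);
        s += post(j, t);
      }
      if (s > 0) for (int j = 0; j < n; ++j) post(j, t) /= s;
    }
  }
  return List::create(_["loglik"] = loglik, _["posterior"] = post);
}
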