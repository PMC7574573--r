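#include <Rcpp.h>
using namespace Rcpp;

// Generic discrete-state HMM kernels operating on a T x K matrix of
// state-conditional log densities. Scaled-probability recursions keep the
// forward pass stable for long sequences.

// [[Rcpp::export]]
double hmm_forward_cpp(NumericMatrix logdens, NumericMatrix A,
                       NumericVector delta) {
  int T = logdens.nrow(), K = logdens.ncol();
  std::vector<double> v(K), vn(K);
  double lscale = 0.0;

  double m = logdens(0, 0);
  for (int k = 1; k < K; ++k) m = std::max(m, logdens(0, k));
  double s = 0.0;
  for (int k = 0; k < K; ++k) {
    v[k] = delta[k] * std::exp(logdens(0, k) - m);
    s += v[k];
  }
  lscale += std::log(s) + m;
  for (int k = 0; k < K; ++k) v[k] /= s;

  for (int t = 1; t < T; ++t) {
    m = logdens(t, 0);
    for (int k = 1; k < K; ++k) m = std::max(m, logdens(t, k));
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double acc = 0.0;
      for (int j = 0; j < K; ++j) acc += v[j] * A(j, k);
      vn[k] = acc * std::exp(logdens(t, k) - m);
      s += vn[k];
    }
    if (s <= 0.0) return R_NegInf;
    lscale += std::log(s) + m;
    for (int k = 0; k < K; ++k) v[k] = vn[k] / s;
  }
  return lscale;
}

// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericMatrix logdens, NumericMatrix A,
                              NumericVector delta) {
  int T = logdens.nrow(), K = logdens.ncol();
  NumericMatrix dp(T, K);
  IntegerMatrix back(T, K);

  for (int k = 0; k < K; ++k)
    dp(0, k) = std::log(delta[k]) + logdens(0, k);

  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf;
      int arg = 0;
      for (int j = 0; j < K; ++j) {
        double cand = dp(t - 1, j) + std::log(A(j, k));
        if (cand > best) { best = cand; arg = j; }
      }
      dp(t, k) = best + logdens(t, k);
      back(t, k) = arg;
    }
  }

  IntegerVector path(T);
  double best = R_NegInf;
  int arg = 0;
  for (int k = 0; k < K; ++k)
    if (dp(T - 1, k) > best) { best = dp(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 1; t > 0; --t) path[t - 1] = back(t, path[t]);
  for (int t = 0; t < T; ++t) path[t] += 1;  // 1-based states
  return path;
}

// [[Rcpp::export]]
NumericMatrix hmm_posteriors_cpp(NumericMatrix logdens, NumericMatrix A,
                                 NumericVector delta) {
  int T = logdens.nrow(), K = logdens.ncol();
  NumericMatrix alpha(T, K), beta(T, K), post(T, K);

  // scaled forward
  double m = logdens(0, 0);
  for (int k = 1; k < K; ++k) m = std::max(m, logdens(0, k));
  double s = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha(0, k) = delta[k] * std::exp(logdens(0, k) - m);
    s += alpha(0, k);
  }
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    m = logdens(t, 0);
    for (int k = 1; k < K; ++k) m = std::max(m, logdens(t, k));
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double acc = 0.0;
      for (int j = 0; j < K; ++j) acc += alpha(t - 1, j) * A(j, k);
      alpha(t, k) = acc * std::exp(logdens(t, k) - m);
      s += alpha(t, k);
    }
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }

  // scaled backward
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    m = logdens(t + 1, 0);
    for (int k = 1; k < K; ++k) m = std::max(m, logdens(t + 1, k));
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double acc = 0.0;
      for (int j = 0; j < K; ++j)
        acc += A(k, j) * std::exp(logdens(t + 1, j) - m) * beta(t + 1, j);
      beta(t, k) = acc;
      s += acc;
    }
    for (int k = 0; k < K; ++k) beta(t, k) /= s;
  }

  for (int t = 0; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      post(t, k) = alpha(t, k) * beta(t, k);
      s += post(t, k);
    }
    for (int k = 0; k < K; ++k) post(t, k) /= s;
  }
  return post;
}
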