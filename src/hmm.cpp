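#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward E-step for one discrete-emission HMM over a set
// of observation sequences (integer symbols, 0-based). Structural zeros in
// A and B propagate: a zero stays zero in every expected count.
// Work matrices are S x T so each time slice is a contiguous column.
//
// Returns total log-likelihood and the expected sufficient statistics
// (transition counts, emission counts, initial-state counts) summed over
// sequences.

// [[Rcpp::export]]
List cpp_hmm_estep(List obs_list, NumericMatrix A, NumericMatrix B,
                   NumericVector pi) {
  const int S = A.nrow();
  NumericMatrix TA(S, S), TB(S, B.ncol());
  NumericVector Tpi(S);
  double loglik = 0.0;

  std::vector<double> alpha, beta, scale;

  for (int s_i = 0; s_i < obs_list.size(); ++s_i) {
    IntegerVector obs = obs_list[s_i];
    const int T = obs.size();
    if (T == 0) continue;
    alpha.assign((size_t)T * S, 0.0);
    beta.assign((size_t)T * S, 0.0);
    scale.assign(T, 0.0);

    // forward
    double c0 = 0.0;
    for (int j = 0; j < S; ++j) {
      alpha[j] = pi[j] * B(j, obs[0]);
      c0 += alpha[j];
    }
    if (c0 <= 0.0) return List::create(_["loglik"] = R_NegInf);
    scale[0] = c0;
    for (int j = 0; j < S; ++j) alpha[j] /= c0;

    for (int t = 1; t < T; ++t) {
      double *prev = &alpha[(size_t)(t - 1) * S];
      double *cur = &alpha[(size_t)t * S];
      double ct = 0.0;
      for (int j = 0; j < S; ++j) {
        double s = 0.0;
        for (int i = 0; i < S; ++i) s += prev[i] * A(i, j);
        cur[j] = s * B(j, obs[t]);
        ct += cur[j];
      }
      if (ct <= 0.0) return List::create(_["loglik"] = R_NegInf);
      scale[t] = ct;
      for (int j = 0; j < S; ++j) cur[j] /= ct;
    }

    // backward
    for (int j = 0; j < S; ++j) beta[(size_t)(T - 1) * S + j] = 1.0;
    for (int t = T - 2; t >= 0; --t) {
      double *nxt = &beta[(size_t)(t + 1) * S];
      double *cur = &beta[(size_t)t * S];
      double inv_c = 1.0 / scale[t + 1];
      for (int i = 0; i < S; ++i) {
        double s = 0.0;
        for (int j = 0; j < S; ++j) s += A(i, j) * B(j, obs[t + 1]) * nxt[j];
        cur[i] = s * inv_c;
      }
    }

    for (int t = 0; t < T; ++t) loglik += std::log(scale[t]);

    // gamma / xi accumulation
    for (int j = 0; j < S; ++j) Tpi[j] += alpha[j] * beta[j];
    for (int t = 0; t < T; ++t) {
      double *a = &alpha[(size_t)t * S];
      double *bt = &beta[(size_t)t * S];
      int o = obs[t];
      for (int j = 0; j < S; ++j) TB(j, o) += a[j] * bt[j];
    }
    for (int t = 0; t < T - 1; ++t) {
      double *a = &alpha[(size_t)t * S];
      double *bn = &beta[(size_t)(t + 1) * S];
      double inv_c = 1.0 / scale[t + 1];
      int o = obs[t + 1];
      for (int i = 0; i < S; ++i) {
        if (a[i] == 0.0) continue;
        for (int j = 0; j < S; ++j) {
          TA(i, j) += a[i] * A(i, j) * B(j, o) * bn[j] * inv_c;
        }
      }
    }
  }

  return List::create(_["loglik"] = loglik, _["TA"] = TA, _["TB"] = TB,
                      _["Tpi"] = Tpi);
}

// Viterbi decoding in log space; ties break toward the lowest state index
// (strict > when scanning candidates in ascending order).

// [[Rcpp::export]]
IntegerVector cpp_viterbi(IntegerVector obs, NumericMatrix logA,
                          NumericMatrix logB, NumericVector logpi) {
  const int S = logA.nrow(), T = obs.size();
  IntegerVector path(T);
  if (T == 0) return path;
  std::vector<double> delta((size_t)T * S);
  std::vector<int> psi((size_t)T * S);

  for (int j = 0; j < S; ++j) delta[j] = logpi[j] + logB(j, obs[0]);
  for (int t = 1; t < T; ++t) {
    double *prev = &delta[(size_t)(t - 1) * S];
    double *cur = &delta[(size_t)t * S];
    int *ps = &psi[(size_t)t * S];
    for (int j = 0; j < S; ++j) {
      double best = R_NegInf;
      int arg = 0;
      for (int i = 0; i < S; ++i) {
        double v = prev[i] + logA(i, j);
        if (v > best) { best = v; arg = i; }
      }
      cur[j] = best + logB(j, obs[t]);
      ps[j] = arg;
    }
  }
  double best = R_NegInf;
  int arg = 0;
  double *last = &delta[(size_t)(T - 1) * S];
  for (int j = 0; j < S; ++j) {
    if (last[j] > best) { best = last[j]; arg = j; }
  }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t)
    path[t] = psi[(size_t)(t + 1) * S + path[t + 1]];
  return path;
}

// Posterior state marginals (forward-backward gammas) for one sequence,
// returned T x S.

// [[Rcpp::export]]
NumericMatrix cpp_hmm_posterior(IntegerVector obs, NumericMatrix A,
                                NumericMatrix B, NumericVector pi) {
  const int S = A.nrow(), T = obs.size();
  NumericMatrix gamma(T, S);
  if (T == 0) return gamma;
  std::vector<double> alpha((size_t)T * S), beta((size_t)T * S), scale(T);

  double c0 = 0.0;
  for (int j = 0; j < S; ++j) {
    alpha[j] = pi[j] * B(j, obs[0]);
    c0 += alpha[j];
  }
  if (c0 <= 0.0) stop("observation impossible under the model");
  scale[0] = c0;
  for (int j = 0; j < S; ++j) alpha[j] /= c0;
  for (int t = 1; t < T; ++t) {
    double *prev = &alpha[(size_t)(t - 1) * S];
    double *cur = &alpha[(size_t)t * S];
    double ct = 0.0;
    for (int j = 0; j < S; ++j) {
      double s = 0.0;
      for (int i = 0; i < S; ++i) s += prev[i] * A(i, j);
      cur[j] = s * B(j, obs[t]);
      ct += cur[j];
    }
    if (ct <= 0.0) stop("observation impossible under the model");
    scale[t] = ct;
    for (int j = 0; j < S; ++j) cur[j] /= ct;
  }
  for (int j = 0; j < S; ++j) beta[(size_t)(T - 1) * S + j] = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    double *nxt = &beta[(size_t)(t + 1) * S];
    double *cur = &beta[(size_t)t * S];
    double inv_c = 1.0 / scale[t + 1];
    for (int i = 0; i < S; ++i) {
      double s = 0.0;
      for (int j = 0; j < S; ++j) s += A(i, j) * B(j, obs[t + 1]) * nxt[j];
      cur[i] = s * inv_c;
    }
  }
  for (int t = 0; t < T; ++t) {
    double tot = 0.0;
    double *a = &alpha[(size_t)t * S];
    double *bt = &beta[(size_t)t * S];
    for (int j = 0; j < S; ++j) tot += a[j] * bt[j];
    for (int j = 0; j < S; ++j) gamma(t, j) = a[j] * bt[j] / tot;
  }
  return gamma;
}
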