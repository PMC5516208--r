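// Linear-chain CRF inner loops: log-space forward-backward, Viterbi, and
// expected-count accumulation. Emission score matrices are computed in R
// (sparse feature matrix times weight matrix); these routines handle the
// per-sentence dynamic programs. Masked transitions are encoded as large
// negative scores (~ -1e30) and vanish in the log-sum-exp.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double NEG_BIG = -1e25; // anything below this is treated as -inf

static inline double logsumexp(const std::vector<double>& v) {
  double m = v[0];
  for (size_t i = 1; i < v.size(); ++i) if (v[i] > m) m = v[i];
  if (m < NEG_BIG) return m;
  double s = 0.0;
  for (size_t i = 0; i < v.size(); ++i) s += std::exp(v[i] - m);
  return m + std::log(s);
}

// forward-backward for one sentence occupying rows [off, off+T) of emis
static double fb_one(const NumericMatrix& emis, int off, int T,
                     const NumericMatrix& trans, const NumericVector& bos,
                     const NumericVector& eos, NumericMatrix& marg,
                     NumericMatrix& trans_exp, NumericVector& bos_exp,
                     NumericVector& eos_exp) {
  const int L = emis.ncol();
  std::vector<double> alpha(T * L), beta(T * L), tmp(L);
  for (int j = 0; j < L; ++j) alpha[j] = bos[j] + emis(off, j);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < L; ++j) {
      for (int i = 0; i < L; ++i) tmp[i] = alpha[(t - 1) * L + i] + trans(i, j);
      alpha[t * L + j] = logsumexp(tmp) + emis(off + t, j);
    }
  }
  for (int j = 0; j < L; ++j) tmp[j] = alpha[(T - 1) * L + j] + eos[j];
  const double logZ = logsumexp(tmp);
  for (int j = 0; j < L; ++j) beta[(T - 1) * L + j] = eos[j];
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < L; ++i) {
      for (int j = 0; j < L; ++j)
        tmp[j] = trans(i, j) + emis(off + t + 1, j) + beta[(t + 1) * L + j];
      beta[t * L + i] = logsumexp(tmp);
    }
  }
  for (int t = 0; t < T; ++t)
    for (int j = 0; j < L; ++j)
      marg(off + t, j) = std::exp(alpha[t * L + j] + beta[t * L + j] - logZ);
  for (int t = 0; t + 1 < T; ++t)
    for (int i = 0; i < L; ++i) {
      const double ai = alpha[t * L + i];
      if (ai < NEG_BIG) continue;
      for (int j = 0; j < L; ++j) {
        const double s = ai + trans(i, j) + emis(off + t + 1, j) +
                         beta[(t + 1) * L + j] - logZ;
        if (s > NEG_BIG) trans_exp(i, j) += std::exp(s);
      }
    }
  for (int j = 0; j < L; ++j) {
    bos_exp[j] += marg(off, j);
    eos_exp[j] += marg(off + T - 1, j);
  }
  return logZ;
}

// [[Rcpp::export]]
List crf_batch_fb(NumericMatrix emis, IntegerVector lengths,
                  NumericMatrix trans, NumericVector bos, NumericVector eos) {
  const int L = emis.ncol(), S = lengths.size();
  NumericMatrix marg(emis.nrow(), L), trans_exp(L, L);
  NumericVector bos_exp(L), eos_exp(L), logZ(S);
  int off = 0;
  for (int s = 0; s < S; ++s) {
    logZ[s] = fb_one(emis, off, lengths[s], trans, bos, eos, marg, trans_exp,
                     bos_exp, eos_exp);
    off += lengths[s];
  }
  return List::create(_["logZ"] = logZ, _["marginals"] = marg,
                      _["trans_exp"] = trans_exp, _["bos_exp"] = bos_exp,
                      _["eos_exp"] = eos_exp);
}

// gold tags are 0-based label indices, concatenated like emis rows
// [[Rcpp::export]]
List crf_gold_counts(NumericMatrix emis, IntegerVector lengths,
                     NumericMatrix trans, NumericVector bos, NumericVector eos,
                     IntegerVector gold) {
  const int L = emis.ncol(), S = lengths.size();
  NumericMatrix trans_emp(L, L);
  NumericVector bos_emp(L), eos_emp(L);
  double score = 0.0;
  int off = 0;
  for (int s = 0; s < S; ++s) {
    const int T = lengths[s];
    score += bos[gold[off]] + emis(off, gold[off]);
    bos_emp[gold[off]] += 1.0;
    for (int t = 1; t < T; ++t) {
      score += trans(gold[off + t - 1], gold[off + t]) + emis(off + t, gold[off + t]);
      trans_emp(gold[off + t - 1], gold[off + t]) += 1.0;
    }
    score += eos[gold[off + T - 1]];
    eos_emp[gold[off + T - 1]] += 1.0;
    off += T;
  }
  return List::create(_["score"] = score, _["trans_emp"] = trans_emp,
                      _["bos_emp"] = bos_emp, _["eos_emp"] = eos_emp);
}

// [[Rcpp::export]]
IntegerVector crf_batch_viterbi(NumericMatrix emis, IntegerVector lengths,
                                NumericMatrix trans, NumericVector bos,
                                NumericVector eos) {
  const int L = emis.ncol(), S = lengths.size();
  IntegerVector out(emis.nrow());
  int off = 0;
  for (int s = 0; s < S; ++s) {
    const int T = lengths[s];
    std::vector<double> delta(T * L);
    std::vector<int> psi(T * L, 0);
    for (int j = 0; j < L; ++j) delta[j] = bos[j] + emis(off, j);
    for (int t = 1; t < T; ++t) {
      for (int j = 0; j < L; ++j) {
        double best = delta[(t - 1) * L] + trans(0, j);
        int arg = 0;
        for (int i = 1; i < L; ++i) {
          const double v = delta[(t - 1) * L + i] + trans(i, j);
          if (v > best) { best = v; arg = i; } // strict >: ties keep lower index
        }
        delta[t * L + j] = best + emis(off + t, j);
        psi[t * L + j] = arg;
      }
    }
    double best = delta[(T - 1) * L] + eos[0];
    int arg = 0;
    for (int j = 1; j < L; ++j) {
      const double v = delta[(T - 1) * L + j] + eos[j];
      if (v > best) { best = v; arg = j; }
    }
    out[off + T - 1] = arg;
    for (int t = T - 1; t > 0; --t) {
      arg = psi[t * L + arg];
      out[off + t - 1] = arg;
    }
    off += T;
  }
  return out;
}
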