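#include <Rcpp.h>
#include <random>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Collapsed Gibbs sampling for LDA.
//
// The sampler owns its RNG (a Mersenne twister seeded from the caller) so
// that results are bit-identical for identical inputs and seed, independent
// of R's RNG state.  Token topic assignments are resampled from
//   p(z = k | rest) \propto (n_dk + alpha_k) * (n_kw + beta) / (n_k + V*beta)
// with theta and phi integrated out.  phi is estimated by averaging the
// smoothed point estimate (n_kw + beta)/(n_k + V*beta) over thinned
// post-burn-in sweeps.

namespace {

struct Tokens {
  std::vector<int> w;     // term index per token instance (0-based)
  std::vector<int> doc;   // document index per token instance (0-based)
};

// Expand sparse (doc, term, count) triplets into per-token instances,
// grouped by document in the order the triplets arrive.
Tokens expand_tokens(const IntegerVector& doc, const IntegerVector& term,
                     const IntegerVector& count) {
  Tokens tk;
  R_xlen_t nnz = doc.size();
  long total = 0;
  for (R_xlen_t i = 0; i < nnz; ++i) total += count[i];
  tk.w.reserve(total);
  tk.doc.reserve(total);
  for (R_xlen_t i = 0; i < nnz; ++i) {
    for (int c = 0; c < count[i]; ++c) {
      tk.w.push_back(term[i]);
      tk.doc.push_back(doc[i]);
    }
  }
  return tk;
}

inline int sample_discrete(const std::vector<double>& p, double total,
                           std::mt19937_64& rng) {
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  double u = unif(rng) * total;
  double cum = 0.0;
  int K = (int)p.size();
  for (int k = 0; k < K; ++k) {
    cum += p[k];
    if (u < cum) return k;
  }
  return K - 1;  // guard against floating-point undershoot
}

}  // namespace

// [[Rcpp::export(name = ".gibbs_train")]]
List gibbs_train(IntegerVector doc, IntegerVector term, IntegerVector count,
                 int D, int V, int K, NumericVector alpha, double beta,
                 int iterations, int burnin, int thin, double seed) {
  Tokens tk = expand_tokens(doc, term, count);
  const long N = (long)tk.w.size();
  if (N == 0) stop("corpus contains no tokens");

  std::mt19937_64 rng((std::uint64_t)seed);
  std::uniform_int_distribution<int> topic_unif(0, K - 1);

  std::vector<int> z(N);
  std::vector<double> ndk((size_t)D * K, 0.0), nkw((size_t)K * V, 0.0),
      nk(K, 0.0);
  for (long i = 0; i < N; ++i) {
    int k = topic_unif(rng);
    z[i] = k;
    ndk[(size_t)tk.doc[i] * K + k] += 1.0;
    nkw[(size_t)k * V + tk.w[i]] += 1.0;
    nk[k] += 1.0;
  }

  std::vector<double> phi_acc((size_t)K * V, 0.0);
  int n_samples = 0;
  std::vector<double> p(K);
  const double Vbeta = (double)V * beta;

  for (int s = 1; s <= iterations; ++s) {
    for (long i = 0; i < N; ++i) {
      const int d = tk.doc[i], w = tk.w[i];
      int k = z[i];
      ndk[(size_t)d * K + k] -= 1.0;
      nkw[(size_t)k * V + w] -= 1.0;
      nk[k] -= 1.0;
      double total = 0.0;
      for (int kk = 0; kk < K; ++kk) {
        double val = (ndk[(size_t)d * K + kk] + alpha[kk]) *
                     (nkw[(size_t)kk * V + w] + beta) / (nk[kk] + Vbeta);
        p[kk] = val;
        total += val;
      }
      k = sample_discrete(p, total, rng);
      z[i] = k;
      ndk[(size_t)d * K + k] += 1.0;
      nkw[(size_t)k * V + w] += 1.0;
      nk[k] += 1.0;
    }
    if (s > burnin && ((s - burnin) % thin == 0)) {
      for (int k = 0; k < K; ++k)
        for (int w = 0; w < V; ++w)
          phi_acc[(size_t)k * V + w] += (nkw[(size_t)k * V + w] + beta) /
                                        (nk[k] + Vbeta);
      ++n_samples;
    }
    if (s % 50 == 0) Rcpp::checkUserInterrupt();
  }
  if (n_samples == 0) {  // degenerate schedule: fall back to the final state
    for (int k = 0; k < K; ++k)
      for (int w = 0; w < V; ++w)
        phi_acc[(size_t)k * V + w] = (nkw[(size_t)k * V + w] + beta) /
                                     (nk[k] + Vbeta);
    n_samples = 1;
  }

  NumericMatrix phi(K, V);
  for (int k = 0; k < K; ++k)
    for (int w = 0; w < V; ++w)
      phi(k, w) = phi_acc[(size_t)k * V + w] / n_samples;
  return List::create(_["phi"] = phi, _["n_samples"] = n_samples,
                      _["n_tokens"] = (double)N);
}

// Fold-in inference: phi held fixed, per-document topic proportions by Gibbs
// over that document's assignments only,
//   p(z = k | rest) \propto (n_dk + alpha_k) * phi_kw,
// theta averaged as (n_dk + alpha_k)/(n_d + sum alpha) over thinned
// post-burn-in sweeps.  Documents are independent: each gets its own RNG
// stream derived from (seed, row), so a row's result does not depend on
// which other rows are inferred alongside it.

// [[Rcpp::export(name = ".gibbs_infer")]]
NumericMatrix gibbs_infer(NumericMatrix phi, IntegerVector doc,
                          IntegerVector term, IntegerVector count, int D,
                          NumericVector alpha, int iterations, int burnin,
                          int thin, double seed) {
  const int K = phi.nrow();
  double alpha_sum = 0.0;
  for (int k = 0; k < K; ++k) alpha_sum += alpha[k];

  // group token instances by document
  std::vector<std::vector<int>> docs((size_t)D);
  for (R_xlen_t i = 0; i < doc.size(); ++i)
    for (int c = 0; c < count[i]; ++c) docs[(size_t)doc[i]].push_back(term[i]);

  NumericMatrix theta(D, K);
  std::vector<double> p(K);

  for (int d = 0; d < D; ++d) {
    const std::vector<int>& w = docs[(size_t)d];
    const int Nd = (int)w.size();
    if (Nd == 0) {  // prior mean
      for (int k = 0; k < K; ++k) theta(d, k) = alpha[k] / alpha_sum;
      continue;
    }
    std::seed_seq seq{(std::uint32_t)((std::uint64_t)seed & 0xffffffffu),
                      (std::uint32_t)d};
    std::mt19937_64 rng(seq);
    std::uniform_int_distribution<int> topic_unif(0, K - 1);
    std::vector<int> z(Nd);
    std::vector<double> ndk(K, 0.0), acc(K, 0.0);
    for (int i = 0; i < Nd; ++i) {
      int k = topic_unif(rng);
      z[i] = k;
      ndk[k] += 1.0;
    }
    int n_samples = 0;
    for (int s = 1; s <= iterations; ++s) {
      for (int i = 0; i < Nd; ++i) {
        int k = z[i];
        ndk[k] -= 1.0;
        double total = 0.0;
        for (int kk = 0; kk < K; ++kk) {
          double val = (ndk[kk] + alpha[kk]) * phi(kk, w[i]);
          p[kk] = val;
          total += val;
        }
        k = sample_discrete(p, total, rng);
        z[i] = k;
        ndk[k] += 1.0;
      }
      if (s > burnin && ((s - burnin) % thin == 0)) {
        for (int k = 0; k < K; ++k) acc[k] += (ndk[k] + alpha[k]) / (Nd + alpha_sum);
        ++n_samples;
      }
    }
    if (n_samples == 0) {
      for (int k = 0; k < K; ++k) acc[k] = (ndk[k] + alpha[k]) / (Nd + alpha_sum);
      n_samples = 1;
    }
    for (int k = 0; k < K; ++k) theta(d, k) = acc[k] / n_samples;
    Rcpp::checkUserInterrupt();
  }
  return theta;
}
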