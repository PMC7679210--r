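#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Self-contained PCG32 generator: collapsed Gibbs must be bit-reproducible
// from an integer seed, independently of R's RNG state.
struct PCG32 {
  uint64_t state;
  uint64_t inc;
  PCG32(uint64_t seed, uint64_t seq = 54u) {
    state = 0u;
    inc = (seq << 1u) | 1u;
    next();
    state += seed;
    next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31u));
  }
  double unif() {
    // strictly inside (0, 1)
    return (next() + 0.5) * (1.0 / 4294967296.0);
  }
};

static inline int sample_discrete(const std::vector<double> &p, double total,
                                  PCG32 &rng) {
  double u = rng.unif() * total;
  double acc = 0.0;
  int K = (int)p.size();
  for (int k = 0; k < K; ++k) {
    acc += p[k];
    if (u <= acc) return k;
  }
  return K - 1;
}

// Collapsed Gibbs sampler for LDA.
// word, doc: parallel 0-based token vectors (one entry per token occurrence).
// Returns posterior-mean phi (K x V) and theta (D x K) over thinned
// post-burn-in samples, or final-state estimates when n_samples == 0,
// plus the final token-topic assignment vector.
// [[Rcpp::export(name = ".lda_gibbs")]]
List lda_gibbs(IntegerVector word, IntegerVector doc, int D, int V, int K,
               double alpha, double beta, int iterations, int burn_in,
               int n_samples, double seed) {
  int N = word.size();
  std::vector<int> z(N);
  std::vector<int> ndk((size_t)D * K, 0), nkw((size_t)K * V, 0), nk(K, 0);
  PCG32 rng((uint64_t)seed);

  for (int i = 0; i < N; ++i) {
    int k = (int)(rng.unif() * K);
    if (k >= K) k = K - 1;
    z[i] = k;
    ndk[(size_t)doc[i] * K + k]++;
    nkw[(size_t)k * V + word[i]]++;
    nk[k]++;
  }

  NumericMatrix phi_acc(K, V), theta_acc(D, K);
  int taken = 0;
  int keep = iterations - burn_in;
  int thin = (n_samples > 0) ? std::max(1, keep / n_samples) : 0;
  double Vbeta = V * beta;
  std::vector<double> p(K);

  for (int it = 1; it <= iterations; ++it) {
    for (int i = 0; i < N; ++i) {
      int w = word[i], d = doc[i], kold = z[i];
      ndk[(size_t)d * K + kold]--;
      nkw[(size_t)kold * V + w]--;
      nk[kold]--;
      double total = 0.0;
      for (int k = 0; k < K; ++k) {
        double val = (ndk[(size_t)d * K + k] + alpha) *
                     (nkw[(size_t)k * V + w] + beta) / (nk[k] + Vbeta);
        p[k] = val;
        total += val;
      }
      int knew = sample_discrete(p, total, rng);
      z[i] = knew;
      ndk[(size_t)d * K + knew]++;
      nkw[(size_t)knew * V + w]++;
      nk[knew]++;
    }
    if (n_samples > 0 && it > burn_in && ((it - burn_in) % thin == 0) &&
        taken < n_samples) {
      taken++;
      for (int k = 0; k < K; ++k)
        for (int w = 0; w < V; ++w)
          phi_acc(k, w) += (nkw[(size_t)k * V + w] + beta) / (nk[k] + Vbeta);
      for (int d = 0; d < D; ++d) {
        double nd = 0.0;
        for (int k = 0; k < K; ++k) nd += ndk[(size_t)d * K + k];
        for (int k = 0; k < K; ++k)
          theta_acc(d, k) += (ndk[(size_t)d * K + k] + alpha) / (nd + K * alpha);
      }
    }
  }

  if (taken == 0) { // final-state estimate
    taken = 1;
    for (int k = 0; k < K; ++k)
      for (int w = 0; w < V; ++w)
        phi_acc(k, w) = (nkw[(size_t)k * V + w] + beta) / (nk[k] + Vbeta);
    for (int d = 0; d < D; ++d) {
      double nd = 0.0;
      for (int k = 0; k < K; ++k) nd += ndk[(size_t)d * K + k];
      for (int k = 0; k < K; ++k)
        theta_acc(d, k) = (ndk[(size_t)d * K + k] + alpha) / (nd + K * alpha);
    }
  }
  for (int k = 0; k < K; ++k)
    for (int w = 0; w < V; ++w) phi_acc(k, w) /= taken;
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < K; ++k) theta_acc(d, k) /= taken;

  IntegerVector zout(N);
  for (int i = 0; i < N; ++i) zout[i] = z[i];
  return List::create(_["phi"] = phi_acc, _["theta"] = theta_acc,
                      _["assignments"] = zout, _["samples_used"] = taken);
}

// Fold-in inference for a single new document: phi held fixed, only the
// document's topic assignments are resampled.
// [[Rcpp::export(name = ".lda_foldin")]]
NumericVector lda_foldin(IntegerVector word, NumericMatrix phi, double alpha,
                         int iterations, int burn_in, int n_samples,
                         double seed) {
  int N = word.size();
  int K = phi.nrow();
  PCG32 rng((uint64_t)seed);
  std::vector<int> z(N), ndk(K, 0);
  for (int i = 0; i < N; ++i) {
    int k = (int)(rng.unif() * K);
    if (k >= K) k = K - 1;
    z[i] = k;
    ndk[k]++;
  }
  NumericVector theta(K);
  int taken = 0;
  int keep = iterations - burn_in;
  int thin = (n_samples > 0) ? std::max(1, keep / n_samples) : 0;
  std::vector<double> p(K);
  for (int it = 1; it <= iterations; ++it) {
    for (int i = 0; i < N; ++i) {
      int w = word[i], kold = z[i];
      ndk[kold]--;
      double total = 0.0;
      for (int k = 0; k < K; ++k) {
        double val = (ndk[k] + alpha) * phi(k, w);
        p[k] = val;
        total += val;
      }
      int knew = sample_discrete(p, total, rng);
      z[i] = knew;
      ndk[knew]++;
    }
    if (n_samples > 0 && it > burn_in && ((it - burn_in) % thin == 0) &&
        taken < n_samples) {
      taken++;
      for (int k = 0; k < K; ++k)
        theta[k] += (ndk[k] + alpha) / (N + K * alpha);
    }
  }
  if (taken == 0) {
    taken = 1;
    for (int k = 0; k < K; ++k) theta[k] = (ndk[k] + alpha) / (N + K * alpha);
  }
  for (int k = 0; k < K; ++k) theta[k] /= taken;
  return theta;
}
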