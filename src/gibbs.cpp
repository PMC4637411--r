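#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

// Heat-bath Gibbs sampler for a pairwise Q-state Markov random field given
// per-edge potential tables H_e(x_i, x_j) (probability ~ exp(-sum H)).
//
// Uses a self-contained splitmix64/xorshift generator seeded from an integer
// so that draws are reproducible across platforms and independent of R's
// RNG state.

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed + 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() {  // in [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  int unifInt(int n) { return static_cast<int>(unif() * n); }
};

}  // namespace

// edges: E x 2 integer matrix, 0-based, i < j
// pot:   E x (Q*Q) matrix, row e = H_e flattened with x_i fastest
//        (pot(e, xi + Q*xj))
// [[Rcpp::export(name = ".gibbs_sample_cpp")]]
Rcpp::IntegerMatrix gibbs_sample_cpp(int N, int Q, int n_samples, int burn_in,
                                     int thin, double seed,
                                     Rcpp::IntegerMatrix edges,
                                     Rcpp::NumericMatrix pot) {
  const int E = edges.nrow();
  // adjacency lists: for each node, incident edge ids and orientation
  std::vector<std::vector<int>> adjEdge(N), adjOther(N);
  std::vector<std::vector<bool>> adjFirst(N);
  for (int e = 0; e < E; ++e) {
    int i = edges(e, 0), j = edges(e, 1);
    adjEdge[i].push_back(e); adjOther[i].push_back(j);
    adjFirst[i].push_back(true);
    adjEdge[j].push_back(e); adjOther[j].push_back(i);
    adjFirst[j].push_back(false);
  }

  Rng rng(static_cast<uint64_t>(seed));
  std::vector<int> x(N);
  for (int i = 0; i < N; ++i) x[i] = rng.unifInt(Q);

  Rcpp::IntegerMatrix out(n_samples, N);
  std::vector<double> en(Q), p(Q);

  const long total = static_cast<long>(burn_in) +
                     static_cast<long>(n_samples) * thin;
  long kept = 0;
  for (long sweep = 0; sweep < total && kept < n_samples; ++sweep) {
    for (int i = 0; i < N; ++i) {
      for (int s = 0; s < Q; ++s) en[s] = 0.0;
      const size_t deg = adjEdge[i].size();
      for (size_t a = 0; a < deg; ++a) {
        const int e = adjEdge[i][a];
        const int xo = x[adjOther[i][a]];
        if (adjFirst[i][a]) {
          for (int s = 0; s < Q; ++s) en[s] += pot(e, s + Q * xo);
        } else {
          for (int s = 0; s < Q; ++s) en[s] += pot(e, xo + Q * s);
        }
      }
      double emin = en[0];
      for (int s = 1; s < Q; ++s) if (en[s] < emin) emin = en[s];
      double z = 0.0;
      for (int s = 0; s < Q; ++s) { p[s] = std::exp(-(en[s] - emin)); z += p[s]; }
      const double u = rng.unif() * z;
      double acc = 0.0;
      int chosen = Q - 1;
      for (int s = 0; s < Q; ++s) {
        acc += p[s];
        if (u < acc) { chosen = s; break; }
      }
      x[i] = chosen;
    }
    if (sweep >= burn_in && (sweep - burn_in) % thin == thin - 1) {
      for (int i = 0; i < N; ++i) out(kept, i) = x[i];
      ++kept;
    }
  }
  return out;
}
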