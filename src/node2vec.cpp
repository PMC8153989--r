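#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Deterministic, platform-stable RNG: xoshiro256++ with its state seeded
// through splitmix64, the reference seeding construction. The walk sampler
// and skip-gram trainer must reproduce bit-identically across machines for
// a given seed, so R's RNG (whose state handling we want to keep out of
// C++ loops) is not used here.
struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    // splitmix64 expands the seed into the 256-bit state
    for (int i = 0; i < 4; ++i) {
      uint64_t z = (seed += 0x9E3779B97F4A7C15ULL);
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next_u64() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform double in [0, 1)
  double unif() { return (next_u64() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  int unif_int(int n) { return (int)(unif() * n); }
};


static inline bool has_edge(const IntegerVector& indptr,
                            const IntegerVector& indices,
                            int a, int b) {
  // neighbours of a are sorted; binary search for b
  int lo = indptr[a], hi = indptr[a + 1] - 1;
  while (lo <= hi) {
    int mid = (lo + hi) / 2;
    if (indices[mid] == b) return true;
    if (indices[mid] < b) lo = mid + 1; else hi = mid - 1;
  }
  return false;
}

// One biased step of a second-order walk: previous node t (or -1 at the
// walk start, where the bias is uniform), current node v. Edge weights are
// multiplied by 1/p for returning to t, 1 for common neighbours of t and
// v, and 1/q for nodes farther from t.
static int biased_step(const IntegerVector& indptr, const IntegerVector& indices,
                       const NumericVector& weights, int t, int v,
                       double p, double q, Xoshiro256pp& rng,
                       std::vector<double>& buf) {
  int beg = indptr[v], end = indptr[v + 1];
  int deg = end - beg;
  if (deg == 0) return -1;
  buf.resize(deg);
  double total = 0.0;
  for (int k = 0; k < deg; ++k) {
    int x = indices[beg + k];
    double alpha;
    if (t < 0) alpha = 1.0;
    else if (x == t) alpha = 1.0 / p;
    else if (has_edge(indptr, indices, t, x)) alpha = 1.0;
    else alpha = 1.0 / q;
    total += alpha * weights[beg + k];
    buf[k] = total;
  }
  double u = rng.unif() * total;
  for (int k = 0; k < deg; ++k) {
    if (u < buf[k]) return indices[beg + k];
  }
  return indices[end - 1];
}

// [[Rcpp::export]]
List cpp_generate_walks(IntegerVector indptr, IntegerVector indices,
                        NumericVector weights, double p, double q,
                        int walk_length, int walks_per_node, double seed) {
  int n = indptr.size() - 1;
  Xoshiro256pp rng((uint64_t)seed);
  std::vector<double> buf;
  List out;
  std::vector<IntegerVector> walks;
  for (int r = 0; r < walks_per_node; ++r) {
    for (int u = 0; u < n; ++u) {
      if (indptr[u + 1] == indptr[u]) continue;  // isolated: skipped upstream
      std::vector<int> walk;
      walk.reserve(walk_length);
      walk.push_back(u);
      int t = -1, v = u;
      while ((int)walk.size() < walk_length) {
        int x = biased_step(indptr, indices, weights, t, v, p, q, rng, buf);
        if (x < 0) break;  // dead end
        walk.push_back(x);
        t = v;
        v = x;
      }
      walks.push_back(wrap(walk));
    }
  }
  return wrap(walks);
}

// Repeatedly sample the next node from (t, v); used to compare the
// sampler's empirical law against the exact step distribution.
// [[Rcpp::export]]
IntegerVector cpp_sample_steps(IntegerVector indptr, IntegerVector indices,
                               NumericVector weights, int t, int v,
                               double p, double q, int n_samples, double seed) {
  Xoshiro256pp rng((uint64_t)seed);
  std::vector<double> buf;
  IntegerVector out(n_samples);
  for (int i = 0; i < n_samples; ++i) {
    out[i] = biased_step(indptr, indices, weights, t, v, p, q, rng, buf);
  }
  return out;
}

static inline double sigmoid(double x) {
  if (x > 6.0) return 1.0;
  if (x < -6.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling over a walk corpus (word2vec-style
// SGD, single-threaded for reproducibility). Walks hold 0-based vocabulary
// indices; the negative-sampling table uses the unigram^(3/4) law.
// [[Rcpp::export]]
NumericMatrix cpp_train_skipgram(List walks, int vocab_size, int dim,
                                 int window, int epochs, int negative,
                                 double alpha, double min_alpha, double seed) {
  Xoshiro256pp rng((uint64_t)seed);
  int n_walks = walks.size();

  // unigram^0.75 cumulative table for negative sampling
  std::vector<double> counts(vocab_size, 0.0);
  long long total_tokens = 0;
  for (int w = 0; w < n_walks; ++w) {
    IntegerVector walk = walks[w];
    total_tokens += walk.size();
    for (int i = 0; i < walk.size(); ++i) counts[walk[i]] += 1.0;
  }
  std::vector<double> cum(vocab_size);
  double tot = 0.0;
  for (int v = 0; v < vocab_size; ++v) {
    tot += std::pow(counts[v], 0.75);
    cum[v] = tot;
  }

  std::vector<double> syn0((size_t)vocab_size * dim);
  std::vector<double> syn1((size_t)vocab_size * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i) {
    syn0[i] = (rng.unif() - 0.5) / dim;
  }

  std::vector<double> grad(dim);
  long long processed = 0;
  long long budget = total_tokens * (long long)epochs;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int w = 0; w < n_walks; ++w) {
      IntegerVector walk = walks[w];
      int len = walk.size();
      for (int i = 0; i < len; ++i) {
        double lr = alpha * (1.0 - (double)processed / (double)(budget + 1));
        if (lr < min_alpha) lr = min_alpha;
        ++processed;
        int center = walk[i];
        int b = rng.unif_int(window);  // reduced-window trick
        for (int j = i - window + b; j <= i + window - b; ++j) {
          if (j == i || j < 0 || j >= len) continue;
          int context = walk[j];
          double* v_in = &syn0[(size_t)context * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int neg = 0; neg <= negative; ++neg) {
            int target;
            double label;
            if (neg == 0) {
              target = center;
              label = 1.0;
            } else {
              double u = rng.unif() * tot;
              int lo = 0, hi = vocab_size - 1;
              while (lo < hi) {
                int mid = (lo + hi) / 2;
                if (cum[mid] <= u) lo = mid + 1; else hi = mid;
              }
              target = lo;
              if (target == center) continue;
              label = 0.0;
            }
            double* v_out = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += v_in[d] * v_out[d];
            double g = (label - sigmoid(dot)) * lr;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * v_out[d];
              v_out[d] += g * v_in[d];
            }
          }
          for (int d = 0; d < dim; ++d) v_in[d] += grad[d];
        }
      }
    }
  }

  NumericMatrix out(vocab_size, dim);
  for (int v = 0; v < vocab_size; ++v) {
    for (int d = 0; d < dim; ++d) out(v, d) = syn0[(size_t)v * dim + d];
  }
  return out;
}
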