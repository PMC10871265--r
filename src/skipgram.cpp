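#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Skip-gram with negative sampling over precomputed random-walk corpora
// (word2vec-style trainer used for biased-random-walk node embeddings).
//
// walks: integer matrix (n_walks x walk_length), 0-based node ids, -1 pads
// short walks. Negative nodes are drawn from the unigram distribution of
// the corpus raised to the 3/4 power. Deterministic under seed (own
// xorshift64* generator; the global R RNG is untouched). Uses a full
// symmetric context window and a learning rate decaying linearly over
// epoch passes. Returns the input (center) vectors, n_nodes x dim.

static inline uint64_t xorshift64(uint64_t &s) {
  s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
  return s * 2685821657736338717ULL;
}
static inline double urand(uint64_t &s) {
  return (xorshift64(s) >> 11) * (1.0 / 9007199254740992.0);
}

// [[Rcpp::export]]
NumericMatrix skipgram_cpp(IntegerMatrix walks, int n_nodes, int dim,
                           int window, int negatives, int epochs,
                           double alpha, int seed) {
  const int n_walks = walks.nrow(), wl = walks.ncol();
  uint64_t rs = (uint64_t)seed * 6364136223846793005ULL + 1442695040888963407ULL;
  for (int k = 0; k < 8; ++k) xorshift64(rs);

  // unigram^0.75 cumulative table
  std::vector<double> freq(n_nodes, 0.0);
  long total_tokens = 0;
  for (int w = 0; w < n_walks; ++w)
    for (int t = 0; t < wl; ++t) {
      int v = walks(w, t);
      if (v >= 0) { freq[v] += 1.0; ++total_tokens; }
    }
  std::vector<double> cum(n_nodes);
  double acc = 0;
  for (int v = 0; v < n_nodes; ++v) { acc += std::pow(freq[v], 0.75); cum[v] = acc; }
  if (acc <= 0) stop("empty walk corpus");
  auto draw_neg = [&](void) {
    double u = urand(rs) * acc;
    int lo = 0, hi = n_nodes - 1;
    while (lo < hi) { int mid = (lo + hi) / 2; if (cum[mid] < u) lo = mid + 1; else hi = mid; }
    return lo;
  };

  std::vector<double> syn0((size_t)n_nodes * dim), syn1((size_t)n_nodes * dim, 0.0);
  for (size_t k = 0; k < syn0.size(); ++k)
    syn0[k] = (urand(rs) - 0.5) / dim;

  std::vector<double> grad(dim);
  const long total_steps = (long)epochs * n_walks;
  long step = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int w = 0; w < n_walks; ++w, ++step) {
      double lr = alpha * (1.0 - (double)step / (double)(total_steps + 1));
      if (lr < alpha * 1e-4) lr = alpha * 1e-4;
      for (int t = 0; t < wl; ++t) {
        int center = walks(w, t);
        if (center < 0) break;
        int lo = t - window < 0 ? 0 : t - window;
        int hi = t + window >= wl ? wl - 1 : t + window;
        for (int c = lo; c <= hi; ++c) {
          if (c == t) continue;
          int ctx = walks(w, c);
          if (ctx < 0) break;
          double *v_in = &syn0[(size_t)center * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int neg = 0; neg <= negatives; ++neg) {
            int target; double label;
            if (neg == 0) { target = ctx; label = 1.0; }
            else {
              target = draw_neg();
              if (target == ctx) continue;
              label = 0.0;
            }
            double *v_out = &syn1[(size_t)target * dim];
            double dot = 0;
            for (int d = 0; d < dim; ++d) dot += v_in[d] * v_out[d];
            double p = 1.0 / (1.0 + std::exp(-dot));
            double g = lr * (label - p);
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

  NumericMatrix out(n_nodes, dim);
  for (int v = 0; v < n_nodes; ++v)
    for (int d = 0; d < dim; ++d) out(v, d) = syn0[(size_t)v * dim + d];
  return out;
}
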