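// Single-worker CBOW / skip-gram trainer with negative sampling.
// Deterministic: all randomness comes from one splitmix64 stream seeded from R.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97f4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform in [0,1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n); n is tiny here so modulo bias is negligible
  int unif_int(int n) { return (int)(next() % (uint64_t)n); }
};

inline double sigmoid(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// draw from the unigram^alpha noise distribution via its cdf
inline int draw_noise(const std::vector<double>& cdf, double u) {
  int lo = 0, hi = (int)cdf.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cdf[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

} // namespace

// [[Rcpp::export(name = ".train_word2vec_cpp")]]
List train_word2vec_cpp(List sentences, int vocab_size, bool cbow, int dim,
                        int window, int negative, int epochs, double seed,
                        double alpha0, double alpha_min, double noise_exp) {
  SplitMix64 rng((uint64_t)seed);

  const int n_sent = sentences.size();
  std::vector<std::vector<int>> sents(n_sent);
  long long n_tokens = 0;
  std::vector<double> counts(vocab_size, 0.0);
  for (int s = 0; s < n_sent; ++s) {
    IntegerVector sv = sentences[s];
    sents[s].assign(sv.begin(), sv.end());
    for (int w : sents[s]) {
      if (w < 0 || w >= vocab_size) stop("token index out of range");
      counts[w] += 1.0;
    }
    n_tokens += sents[s].size();
  }
  if (n_tokens == 0) stop("empty corpus");

  std::vector<double> cdf(vocab_size);
  double tot = 0.0;
  for (int v = 0; v < vocab_size; ++v) tot += std::pow(counts[v], noise_exp);
  double acc = 0.0;
  for (int v = 0; v < vocab_size; ++v) {
    acc += std::pow(counts[v], noise_exp) / tot;
    cdf[v] = acc;
  }
  cdf[vocab_size - 1] = 1.0;

  // syn0: input embeddings (returned); syn1: output weights
  std::vector<double> syn0((size_t)vocab_size * dim);
  std::vector<double> syn1((size_t)vocab_size * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  const double total_updates = (double)epochs * (double)n_tokens;
  long long processed = 0;
  NumericVector epoch_loss(epochs);

  std::vector<double> h(dim), neu1e(dim);
  std::vector<int> targets;   // positive first, then negatives
  std::vector<int> labels;

  for (int ep = 0; ep < epochs; ++ep) {
    double loss_sum = 0.0;
    long long loss_n = 0;
    for (int s = 0; s < n_sent; ++s) {
      const std::vector<int>& sent = sents[s];
      const int L = (int)sent.size();
      for (int t = 0; t < L; ++t) {
        double alpha = alpha0 * (1.0 - (double)processed / total_updates);
        if (alpha < alpha_min) alpha = alpha_min;
        ++processed;

        const int b = rng.unif_int(window);   // shrink window: effective size window - b
        const int win = window - b;
        int lo = t - win; if (lo < 0) lo = 0;
        int hi = t + win; if (hi > L - 1) hi = L - 1;
        const int center = sent[t];

        if (cbow) {
          int cc = 0;
          std::fill(h.begin(), h.end(), 0.0);
          for (int p = lo; p <= hi; ++p) {
            if (p == t) continue;
            const double* v0 = &syn0[(size_t)sent[p] * dim];
            for (int d = 0; d < dim; ++d) h[d] += v0[d];
            ++cc;
          }
          if (cc == 0) continue;
          for (int d = 0; d < dim; ++d) h[d] /= cc;

          targets.clear(); labels.clear();
          targets.push_back(center); labels.push_back(1);
          for (int k = 0; k < negative; ++k) {
            int neg = draw_noise(cdf, rng.unif());
            if (neg == center) continue;      // word2vec convention: skip, do not redraw
            targets.push_back(neg); labels.push_back(0);
          }
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (size_t k = 0; k < targets.size(); ++k) {
            double* v1 = &syn1[(size_t)targets[k] * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += h[d] * v1[d];
            const double f = sigmoid(dot);
            loss_sum += labels[k] ? -std::log(std::max(f, 1e-12))
                                  : -std::log(std::max(1.0 - f, 1e-12));
            const double g = (labels[k] - f) * alpha;  // -alpha * dL/ddot
            for (int d = 0; d < dim; ++d) neu1e[d] += g * v1[d];
            for (int d = 0; d < dim; ++d) v1[d] += g * h[d];
          }
          ++loss_n;
          // exact mean-context gradient: distribute error / context count
          for (int p = lo; p <= hi; ++p) {
            if (p == t) continue;
            double* v0 = &syn0[(size_t)sent[p] * dim];
            for (int d = 0; d < dim; ++d) v0[d] += neu1e[d] / cc;
          }
        } else {  // skip-gram: center's input vector predicts each context word
          for (int p = lo; p <= hi; ++p) {
            if (p == t) continue;
            const int ctx = sent[p];
            targets.clear(); labels.clear();
            targets.push_back(ctx); labels.push_back(1);
            for (int k = 0; k < negative; ++k) {
              int neg = draw_noise(cdf, rng.unif());
              if (neg == ctx) continue;
              targets.push_back(neg); labels.push_back(0);
            }
            double* v0 = &syn0[(size_t)center * dim];
            std::fill(neu1e.begin(), neu1e.end(), 0.0);
            for (size_t k = 0; k < targets.size(); ++k) {
              double* v1 = &syn1[(size_t)targets[k] * dim];
              double dot = 0.0;
              for (int d = 0; d < dim; ++d) dot += v0[d] * v1[d];
              const double f = sigmoid(dot);
              loss_sum += labels[k] ? -std::log(std::max(f, 1e-12))
                                    : -std::log(std::max(1.0 - f, 1e-12));
              const double g = (labels[k] - f) * alpha;
              for (int d = 0; d < dim; ++d) neu1e[d] += g * v1[d];
              for (int d = 0; d < dim; ++d) v1[d] += g * v0[d];
            }
            ++loss_n;
            for (int d = 0; d < dim; ++d) v0[d] += neu1e[d];
          }
        }
      }
    }
    epoch_loss[ep] = loss_n > 0 ? loss_sum / loss_n : NA_REAL;
  }

  NumericMatrix out(vocab_size, dim);
  for (int v = 0; v < vocab_size; ++v)
    for (int d = 0; d < dim; ++d)
      out(v, d) = syn0[(size_t)v * dim + d];
  return List::create(_["vectors"] = out, _["epoch_loss"] = epoch_loss);
}
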