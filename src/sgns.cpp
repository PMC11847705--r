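// Skip-gram with negative sampling for concept-code "day sentences".
// Single-threaded on purpose: embedding training must be bit-reproducible
// given a seed, which multi-worker schedules cannot guarantee.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

// xorshift64* PRNG: deterministic across platforms, independent of R's RNG
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

}  // namespace

// [[Rcpp::export]]
NumericMatrix sgns_train_cpp(List sentences, int vocab_size, int dim,
                             IntegerVector counts, int window, int negative,
                             int epochs, double lr_start, double lr_min,
                             double seed) {
  const int V = vocab_size, D = dim;
  Rng rng(static_cast<uint64_t>(seed) * 6364136223846793005ULL + 1442695040888963407ULL);

  std::vector<double> syn0(static_cast<size_t>(V) * D);
  std::vector<double> syn1(static_cast<size_t>(V) * D, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / D;

  // unigram^0.75 negative-sampling table
  const int table_size = 1 << 17;
  std::vector<int> table(table_size);
  double total = 0.0;
  for (int v = 0; v < V; ++v) total += std::pow((double)counts[v], 0.75);
  {
    int v = 0;
    double cum = std::pow((double)counts[0], 0.75) / total;
    for (int i = 0; i < table_size; ++i) {
      table[i] = v;
      if ((i + 1.0) / table_size > cum && v < V - 1) {
        ++v;
        cum += std::pow((double)counts[v], 0.75) / total;
      }
    }
  }

  // total word count for the linear learning-rate schedule
  long long corpus_words = 0;
  const int S = sentences.size();
  std::vector<IntegerVector> sent(S);
  for (int s = 0; s < S; ++s) {
    sent[s] = sentences[s];
    corpus_words += sent[s].size();
  }
  const long long train_words = corpus_words * (long long)epochs;
  long long processed = 0;

  std::vector<double> grad(D);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < S; ++s) {
      const IntegerVector& w = sent[s];
      const int L = w.size();
      for (int i = 0; i < L; ++i) {
        ++processed;
        double lr = lr_start - (lr_start - lr_min) * ((double)processed / train_words);
        const int b = rng.below(window);  // dynamic window shrink
        const int center = w[i] - 1;
        for (int j = i - window + b; j <= i + window - b; ++j) {
          if (j == i || j < 0 || j >= L) continue;
          const int context = w[j] - 1;
          double* v_in = &syn0[(size_t)center * D];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int nidx = 0; nidx <= negative; ++nidx) {
            int target;
            double label;
            if (nidx == 0) { target = context; label = 1.0; }
            else {
              target = table[rng.below(table_size)];
              if (target == context) continue;
              label = 0.0;
            }
            double* v_out = &syn1[(size_t)target * D];
            double dot = 0.0;
            for (int dIdx = 0; dIdx < D; ++dIdx) dot += v_in[dIdx] * v_out[dIdx];
            const double pred = 1.0 / (1.0 + std::exp(-dot));
            const double g = (label - pred) * lr;
            for (int dIdx = 0; dIdx < D; ++dIdx) {
              grad[dIdx] += g * v_out[dIdx];
              v_out[dIdx] += g * v_in[dIdx];
            }
          }
          for (int dIdx = 0; dIdx < D; ++dIdx) v_in[dIdx] += grad[dIdx];
        }
      }
    }
  }

  NumericMatrix out(V, D);
  for (int v = 0; v < V; ++v)
    for (int dIdx = 0; dIdx < D; ++dIdx)
      out(v, dIdx) = syn0[(size_t)v * D + dIdx];
  return out;
}
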