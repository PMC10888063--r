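// Continuous-bag-of-words embeddings with negative sampling.
// Single-threaded with a self-contained xorshift RNG so that training is
// bit-reproducible for a given (corpus, hyperparameters, seed) triple.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int upto(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// sentences: list of 0-based integer vectors over a vocabulary of size V
// counts:    corpus frequency of each vocabulary word (length V)
// Returns the input (context) and output (center-word) embedding matrices.
// [[Rcpp::export]]
List cbow_train_cpp(List sentences, IntegerVector counts, int dim,
                    int window, int epochs, int negative,
                    double learning_rate, int seed) {
  const int V = counts.size();
  if (V < 2) stop("vocabulary too small to train embeddings");

  // unigram^(3/4) table for negative sampling
  const int TBL = 100000;
  std::vector<int> table(TBL);
  double z = 0.0;
  for (int i = 0; i < V; ++i) z += std::pow(static_cast<double>(counts[i]), 0.75);
  {
    int i = 0;
    double cum = std::pow(static_cast<double>(counts[0]), 0.75) / z;
    for (int t = 0; t < TBL; ++t) {
      double p = (t + 0.5) / TBL;
      while (p > cum && i < V - 1) {
        ++i;
        cum += std::pow(static_cast<double>(counts[i]), 0.75) / z;
      }
      table[t] = i;
    }
  }

  XorShift rng(static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL + 1ULL);
  std::vector<double> syn0(static_cast<size_t>(V) * dim);
  std::vector<double> syn1(static_cast<size_t>(V) * dim, 0.0);
  for (size_t j = 0; j < syn0.size(); ++j) syn0[j] = (rng.unif() - 0.5) / dim;

  std::vector<std::vector<int>> sents;
  sents.reserve(sentences.size());
  long long total_words = 0;
  for (int i = 0; i < sentences.size(); ++i) {
    IntegerVector sv = sentences[i];
    std::vector<int> s(sv.begin(), sv.end());
    for (int w : s) {
      if (w < 0 || w >= V) stop("token id out of range");
    }
    total_words += static_cast<long long>(s.size());
    sents.push_back(std::move(s));
  }
  if (total_words == 0) stop("no trainable tokens");

  const long long grand_total = static_cast<long long>(epochs) * total_words;
  long long processed = 0;
  std::vector<double> h(dim), e(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (const std::vector<int>& sent : sents) {
      const int n = static_cast<int>(sent.size());
      for (int pos = 0; pos < n; ++pos) {
        double lr = learning_rate *
            (1.0 - static_cast<double>(processed) / (grand_total + 1.0));
        if (lr < learning_rate * 1e-4) lr = learning_rate * 1e-4;
        ++processed;

        const int b = rng.upto(window);  // dynamic window shrink
        const int lo = std::max(0, pos - window + b);
        const int hi = std::min(n - 1, pos + window - b);
        int cw = 0;
        std::fill(h.begin(), h.end(), 0.0);
        for (int j = lo; j <= hi; ++j) {
          if (j == pos) continue;
          const double* v = &syn0[static_cast<size_t>(sent[j]) * dim];
          for (int d = 0; d < dim; ++d) h[d] += v[d];
          ++cw;
        }
        if (cw == 0) continue;
        for (int d = 0; d < dim; ++d) h[d] /= cw;

        std::fill(e.begin(), e.end(), 0.0);
        const int target = sent[pos];
        for (int k = 0; k <= negative; ++k) {
          int wo, label;
          if (k == 0) {
            wo = target;
            label = 1;
          } else {
            wo = table[rng.upto(TBL)];
            if (wo == target) continue;
            label = 0;
          }
          double* v1 = &syn1[static_cast<size_t>(wo) * dim];
          double f = 0.0;
          for (int d = 0; d < dim; ++d) f += h[d] * v1[d];
          const double g = (label - sigmoid(f)) * lr;
          for (int d = 0; d < dim; ++d) {
            e[d] += g * v1[d];
            v1[d] += g * h[d];
          }
        }
        for (int j = lo; j <= hi; ++j) {
          if (j == pos) continue;
          double* v = &syn0[static_cast<size_t>(sent[j]) * dim];
          for (int d = 0; d < dim; ++d) v[d] += e[d];
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix in_mat(V, dim), out_mat(V, dim);
  for (int i = 0; i < V; ++i) {
    for (int d = 0; d < dim; ++d) {
      in_mat(i, d) = syn0[static_cast<size_t>(i) * dim + d];
      out_mat(i, d) = syn1[static_cast<size_t>(i) * dim + d];
    }
  }
  return List::create(Named("input") = in_mat, Named("output") = out_mat);
}
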