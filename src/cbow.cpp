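// Continuous bag-of-words (CBOW) word2vec trainer with negative sampling.
// Single-threaded with a self-contained 64-bit LCG so that, for a fixed
// seed, the learned vectors are bitwise reproducible across runs and
// platforms.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline uint64_t lcg_next(uint64_t &s) {
  s = s * 6364136223846793005ULL + 1442695040888963407ULL;
  return s;
}

static inline double lcg_unif(uint64_t &s) {
  return static_cast<double>(lcg_next(s) >> 11) / 9007199254740992.0; // 2^53
}

static inline double sigmoidf(double x) {
  if (x > 10.0) return 1.0;
  if (x < -10.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// sentences: list of integer vectors, 0-based vocabulary indices, -1 = OOV
// counts: corpus frequency per vocabulary entry (negative-sampling weights
// are counts^0.75). Returns the input-vector table (vocab x dim).
// [[Rcpp::export(name = ".cbowTrain")]]
NumericMatrix cbowTrain(List sentences, int vocabSize, NumericVector counts,
                        int dim, int window, int negative, int epochs,
                        double alpha, int seed) {
  if (vocabSize <= 0) stop("empty vocabulary");
  const int nSent = sentences.size();

  // cumulative distribution for unigram^0.75 negative sampling
  std::vector<double> cdf(vocabSize);
  double tot = 0.0;
  for (int i = 0; i < vocabSize; ++i) {
    tot += std::pow(counts[i], 0.75);
    cdf[i] = tot;
  }

  uint64_t rng = 0x9E3779B97F4A7C15ULL ^ static_cast<uint64_t>(seed);
  lcg_next(rng); // warm up

  std::vector<double> syn0(static_cast<size_t>(vocabSize) * dim);
  std::vector<double> syn1(static_cast<size_t>(vocabSize) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i) {
    syn0[i] = (lcg_unif(rng) - 0.5) / dim;
  }

  // total effective words for the linear learning-rate decay
  long long totalWords = 0;
  std::vector<std::vector<int> > sents(nSent);
  for (int s = 0; s < nSent; ++s) {
    IntegerVector v = sentences[s];
    sents[s].assign(v.begin(), v.end());
    for (int j = 0; j < v.size(); ++j) if (v[j] >= 0) ++totalWords;
  }
  totalWords *= static_cast<long long>(epochs);
  if (totalWords == 0) stop("corpus has no in-vocabulary tokens");

  std::vector<double> h(dim), neu1e(dim);
  long long processed = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < nSent; ++s) {
      const std::vector<int> &sent = sents[s];
      const int len = static_cast<int>(sent.size());
      for (int t = 0; t < len; ++t) {
        const int target = sent[t];
        if (target < 0) continue;
        double lr = alpha *
          (1.0 - static_cast<double>(processed) / (totalWords + 1.0));
        if (lr < alpha * 1e-4) lr = alpha * 1e-4;
        ++processed;

        // gather context
        int cw = 0;
        std::fill(h.begin(), h.end(), 0.0);
        int lo = std::max(0, t - window), hi = std::min(len - 1, t + window);
        std::vector<int> ctx;
        for (int j = lo; j <= hi; ++j) {
          if (j == t || sent[j] < 0) continue;
          ctx.push_back(sent[j]);
          const double *v0 = &syn0[static_cast<size_t>(sent[j]) * dim];
          for (int d = 0; d < dim; ++d) h[d] += v0[d];
          ++cw;
        }
        if (cw == 0) continue;
        for (int d = 0; d < dim; ++d) h[d] /= cw;

        std::fill(neu1e.begin(), neu1e.end(), 0.0);
        for (int k = 0; k <= negative; ++k) {
          int out;
          double label;
          if (k == 0) {
            out = target;
            label = 1.0;
          } else {
            double u = lcg_unif(rng) * tot;
            out = static_cast<int>(
              std::lower_bound(cdf.begin(), cdf.end(), u) - cdf.begin());
            if (out >= vocabSize) out = vocabSize - 1;
            if (out == target) continue;
            label = 0.0;
          }
          double *v1 = &syn1[static_cast<size_t>(out) * dim];
          double f = 0.0;
          for (int d = 0; d < dim; ++d) f += h[d] * v1[d];
          const double g = (label - sigmoidf(f)) * lr;
          for (int d = 0; d < dim; ++d) {
            neu1e[d] += g * v1[d];
            v1[d] += g * h[d];
          }
        }
        for (size_t c = 0; c < ctx.size(); ++c) {
          double *v0 = &syn0[static_cast<size_t>(ctx[c]) * dim];
          for (int d = 0; d < dim; ++d) v0[d] += neu1e[d];
        }
      }
    }
  }

  NumericMatrix out(vocabSize, dim);
  for (int i = 0; i < vocabSize; ++i) {
    for (int d = 0; d < dim; ++d) {
      out(i, d) = syn0[static_cast<size_t>(i) * dim + d];
    }
  }
  return out;
}
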