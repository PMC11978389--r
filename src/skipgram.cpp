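// Skip-gram with negative sampling (SGNS), single-threaded and fully
// deterministic given (corpus, params, seed). Follows the classic word2vec
// training loop: dynamic context window, unigram^0.75 negative-sampling
// table, linearly decaying learning rate.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static inline std::uint64_t next_rand(std::uint64_t &state) {
  // xorshift64* — deterministic across platforms
  state ^= state >> 12;
  state ^= state << 25;
  state ^= state >> 27;
  return state * 2685821657736338717ULL;
}

static inline double runif01(std::uint64_t &state) {
  return (next_rand(state) >> 11) * (1.0 / 9007199254740992.0);
}

static inline double sigmoid(double x) {
  if (x > 6.0) return 1.0;
  if (x < -6.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// [[Rcpp::export(name = ".sgns_train_cpp")]]
List sgns_train_cpp(List sentences, int vocab_size,
                    NumericVector counts, int dim, int window,
                    int negative, int epochs, double alpha,
                    double subsample, int seed) {
  const double min_alpha = alpha * 1e-4;
  std::uint64_t rng = static_cast<std::uint64_t>(seed) * 6364136223846793005ULL + 1442695040888963407ULL;
  if (rng == 0) rng = 88172645463325252ULL;

  // negative-sampling table over unigram counts^0.75
  const int table_size = 1 << 20;
  std::vector<int> table(table_size);
  {
    double total = 0.0;
    for (int i = 0; i < vocab_size; ++i) total += std::pow(counts[i], 0.75);
    int i = 0;
    double cum = std::pow(counts[0], 0.75) / total;
    for (int t = 0; t < table_size; ++t) {
      table[t] = i;
      if ((t + 1.0) / table_size > cum && i < vocab_size - 1) {
        ++i;
        cum += std::pow(counts[i], 0.75) / total;
      }
    }
  }

  std::vector<double> syn0(static_cast<size_t>(vocab_size) * dim);
  std::vector<double> syn1(static_cast<size_t>(vocab_size) * dim, 0.0);
  for (size_t k = 0; k < syn0.size(); ++k) {
    syn0[k] = (runif01(rng) - 0.5) / dim;
  }

  long long total_words = 0;
  double corpus_tokens = 0.0;
  const int n_sent = sentences.size();
  std::vector<IntegerVector> sents(n_sent);
  for (int s = 0; s < n_sent; ++s) {
    sents[s] = sentences[s];
    total_words += sents[s].size();
  }
  total_words *= epochs;
  if (total_words == 0) {
    return List::create(Named("input") = NumericMatrix(vocab_size, dim),
                        Named("output") = NumericMatrix(vocab_size, dim));
  }
  for (int i = 0; i < vocab_size; ++i) corpus_tokens += counts[i];

  // word2vec frequent-word subsampling: keep token w with probability
  // (sqrt(f/t) + 1) * t/f where f is w's relative frequency
  std::vector<double> keep_prob(vocab_size, 1.0);
  if (subsample > 0) {
    for (int i = 0; i < vocab_size; ++i) {
      const double f = counts[i] / corpus_tokens;
      double p = (std::sqrt(f / subsample) + 1.0) * subsample / f;
      keep_prob[i] = p < 1.0 ? p : 1.0;
    }
  }

  std::vector<double> grad(dim);
  std::vector<int> kept;
  long long processed = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n_sent; ++s) {
      const IntegerVector &sen = sents[s];
      kept.clear();
      for (int i = 0; i < sen.size(); ++i) {
        ++processed; // discarded tokens still advance the lr schedule
        const int w = sen[i];
        if (keep_prob[w] >= 1.0 || runif01(rng) < keep_prob[w]) kept.push_back(w);
      }
      const int len = static_cast<int>(kept.size());
      for (int pos = 0; pos < len; ++pos) {
        double lr = alpha * (1.0 - static_cast<double>(processed) / (total_words + 1.0));
        if (lr < min_alpha) lr = min_alpha;
        const int word = kept[pos];
        const int reduced = static_cast<int>(next_rand(rng) % static_cast<std::uint64_t>(window));
        for (int a = reduced; a < window * 2 + 1 - reduced; ++a) {
          if (a == window) continue;
          const int c = pos - window + a;
          if (c < 0 || c >= len) continue;
          const int ctx = kept[c];
          double *v_in = &syn0[static_cast<size_t>(ctx) * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int d = 0; d < negative + 1; ++d) {
            int target; double label;
            if (d == 0) {
              target = word; label = 1.0;
            } else {
              target = table[next_rand(rng) % table_size];
              if (target == word) continue;
              label = 0.0;
            }
            double *v_out = &syn1[static_cast<size_t>(target) * dim];
            double dot = 0.0;
            for (int k = 0; k < dim; ++k) dot += v_in[k] * v_out[k];
            const double g = (label - sigmoid(dot)) * lr;
            for (int k = 0; k < dim; ++k) {
              grad[k] += g * v_out[k];
              v_out[k] += g * v_in[k];
            }
          }
          for (int k = 0; k < dim; ++k) v_in[k] += grad[k];
        }
      }
    }
  }

  NumericMatrix in_mat(vocab_size, dim), out_mat(vocab_size, dim);
  for (int i = 0; i < vocab_size; ++i) {
    for (int k = 0; k < dim; ++k) {
      in_mat(i, k) = syn0[static_cast<size_t>(i) * dim + k];
      out_mat(i, k) = syn1[static_cast<size_t>(i) * dim + k];
    }
  }
  return List::create(Named("input") = in_mat, Named("output") = out_mat);
}
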