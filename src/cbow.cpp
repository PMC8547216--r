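#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Deterministic, platform-independent RNG (splitmix64) so that training is
// reproducible from a single integer seed regardless of R's RNG state.
struct SplitMix64 {
  uint64_t state;
  explicit SplitMix64(uint64_t seed) : state(seed) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform in [0, 1)
  double unif() {
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
};

static inline double sigmoid(double x) {
  return 1.0 / (1.0 + std::exp(-x));
}

// Draw an index from the noise distribution given its CDF (binary search).
static int sample_cdf(const std::vector<double>& cdf, SplitMix64& rng) {
  double u = rng.unif();
  int lo = 0, hi = (int)cdf.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cdf[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

// CBOW with negative sampling over integer-coded sentences (0-based token
// ids). Matrices are dim x vocab (one column per token) for contiguous
// column access. Context is up to `window` tokens each side, truncated at
// sentence edges; hidden vector is the mean of the context input vectors.
// Learning rate decays linearly from lr_initial to lr_final over the total
// number of token updates. Single-threaded; deterministic given `seed`.
// [[Rcpp::export]]
List cbow_train_cpp(List sentences, int vocab_size, NumericVector noise_prob,
                    int dim, int window, int negative, int epochs,
                    double lr_initial, double lr_final, int seed) {
  SplitMix64 rng(0x5DEECE66DULL + (uint64_t)(uint32_t)seed * 0x2545F4914F6CDD1DULL);

  std::vector<double> cdf(vocab_size);
  double acc = 0.0;
  for (int i = 0; i < vocab_size; ++i) { acc += noise_prob[i]; cdf[i] = acc; }
  for (int i = 0; i < vocab_size; ++i) cdf[i] /= acc;

  NumericMatrix in_mat(dim, vocab_size);
  NumericMatrix out_mat(dim, vocab_size);
  double span = 0.5 / dim;
  for (int j = 0; j < vocab_size; ++j)
    for (int d = 0; d < dim; ++d)
      in_mat(d, j) = (rng.unif() * 2.0 - 1.0) * span;
  // out_mat stays zero-initialised

  // total target positions (sentences of length >= 2 contribute all positions)
  long long total_updates = 0;
  int n_sent = sentences.size();
  std::vector<std::vector<int>> sents(n_sent);
  for (int s = 0; s < n_sent; ++s) {
    IntegerVector iv = sentences[s];
    sents[s].assign(iv.begin(), iv.end());
    if (iv.size() >= 2) total_updates += iv.size();
  }
  total_updates *= epochs;
  if (total_updates == 0)
    stop("no trainable positions: need at least one sentence with >= 2 tokens");

  std::vector<double> h(dim), grad_h(dim);
  long long processed = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n_sent; ++s) {
      const std::vector<int>& sent = sents[s];
      int len = (int)sent.size();
      if (len < 2) continue;
      for (int t = 0; t < len; ++t) {
        double lr = lr_initial +
          (lr_final - lr_initial) * ((double)processed / (double)total_updates);
        ++processed;

        int lo = t - window; if (lo < 0) lo = 0;
        int hi = t + window; if (hi > len - 1) hi = len - 1;
        int n_ctx = hi - lo + 1 - 1;  // excludes the target position
        if (n_ctx <= 0) continue;

        for (int d = 0; d < dim; ++d) { h[d] = 0.0; grad_h[d] = 0.0; }
        for (int c = lo; c <= hi; ++c) {
          if (c == t) continue;
          const double* col = &in_mat(0, sent[c]);
          for (int d = 0; d < dim; ++d) h[d] += col[d];
        }
        for (int d = 0; d < dim; ++d) h[d] /= n_ctx;

        int target = sent[t];
        for (int k = 0; k <= negative; ++k) {
          int o;
          double label;
          if (k == 0) { o = target; label = 1.0; }
          else {
            o = sample_cdf(cdf, rng);
            int guard = 0;
            while (o == target && vocab_size > 1 && ++guard < 100)
              o = sample_cdf(cdf, rng);
            label = 0.0;
          }
          double* col = &out_mat(0, o);
          double dot = 0.0;
          for (int d = 0; d < dim; ++d) dot += h[d] * col[d];
          double g = (label - sigmoid(dot)) * lr;
          for (int d = 0; d < dim; ++d) {
            grad_h[d] += g * col[d];
            col[d] += g * h[d];
          }
        }
        for (int c = lo; c <= hi; ++c) {
          if (c == t) continue;
          double* col = &in_mat(0, sent[c]);
          for (int d = 0; d < dim; ++d) col[d] += grad_h[d] / n_ctx;
        }
      }
    }
  }

  return List::create(_["in_mat"] = in_mat, _["out_mat"] = out_mat,
                      _["total_updates"] = (double)total_updates);
}

// Loss of one CBOW negative-sampling example:
//   L = -log sigma(h . v_t) - sum_j log sigma(-h . v_nj),  h = mean context
// in-vectors. Matrices dim x vocab; indices 0-based.
// [[Rcpp::export]]
double cbow_example_loss_cpp(NumericMatrix in_mat, NumericMatrix out_mat,
                             IntegerVector context, int target,
                             IntegerVector negatives) {
  int dim = in_mat.nrow();
  int n_ctx = context.size();
  std::vector<double> h(dim, 0.0);
  for (int i = 0; i < n_ctx; ++i)
    for (int d = 0; d < dim; ++d) h[d] += in_mat(d, context[i]);
  for (int d = 0; d < dim; ++d) h[d] /= n_ctx;

  double dot = 0.0;
  for (int d = 0; d < dim; ++d) dot += h[d] * out_mat(d, target);
  double loss = -std::log(sigmoid(dot));
  for (int j = 0; j < negatives.size(); ++j) {
    double dn = 0.0;
    for (int d = 0; d < dim; ++d) dn += h[d] * out_mat(d, negatives[j]);
    loss -= std::log(sigmoid(-dn));
  }
  return loss;
}

// Analytic gradients of the same example loss with respect to the context
// in-vectors (shared gradient grad_h / n_ctx) and the output vectors of the
// target and each negative. Returned as dim-length vectors / dim x k matrix.
// [[Rcpp::export]]
List cbow_example_grad_cpp(NumericMatrix in_mat, NumericMatrix out_mat,
                           IntegerVector context, int target,
                           IntegerVector negatives) {
  int dim = in_mat.nrow();
  int n_ctx = context.size();
  int n_neg = negatives.size();
  std::vector<double> h(dim, 0.0);
  for (int i = 0; i < n_ctx; ++i)
    for (int d = 0; d < dim; ++d) h[d] += in_mat(d, context[i]);
  for (int d = 0; d < dim; ++d) h[d] /= n_ctx;

  NumericVector grad_h(dim);
  NumericMatrix grad_out(dim, 1 + n_neg);  // col 0 = target, then negatives
  for (int k = 0; k <= n_neg; ++k) {
    int o = (k == 0) ? target : negatives[k - 1];
    double label = (k == 0) ? 1.0 : 0.0;
    double dot = 0.0;
    for (int d = 0; d < dim; ++d) dot += h[d] * out_mat(d, o);
    double f = sigmoid(dot);
    for (int d = 0; d < dim; ++d) {
      grad_h[d] += (f - label) * out_mat(d, o);
      grad_out(d, k) = (f - label) * h[d];
    }
  }
  NumericVector grad_in(dim);
  for (int d = 0; d < dim; ++d) grad_in[d] = grad_h[d] / n_ctx;
  return List::create(_["grad_in_context"] = grad_in, _["grad_out"] = grad_out);
}
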