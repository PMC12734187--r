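// Skip-gram with negative sampling over random-walk corpora.
// Self-contained SGD trainer (word2vec-style): input/output vector tables,
// unigram^{0.75} noise distribution, linear learning-rate decay, fixed
// context window. Deterministic for a given seed.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double fast_sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// walks: one walk per row, 1-based node ids, 0 = padding past a dead end.
// [[Rcpp::export]]
NumericMatrix sgns_embed(IntegerMatrix walks, int n_nodes, int dim,
                         int window, int epochs, int negative,
                         double lr0, int seed) {
  if (dim <= 0) stop("embedding dimension must be positive");
  if (window <= 0) stop("context window must be positive");
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<double> vin(static_cast<size_t>(n_nodes) * dim);
  std::vector<double> vout(static_cast<size_t>(n_nodes) * dim, 0.0);
  for (auto &w : vin) w = (unif(rng) - 0.5) / dim;

  // unigram^{0.75} sampling table
  std::vector<double> cnt(n_nodes, 0.0);
  const int nwalk = walks.nrow(), len = walks.ncol();
  long long tokens = 0;
  for (int i = 0; i < nwalk; ++i)
    for (int j = 0; j < len; ++j)
      if (walks(i, j) > 0) { cnt[walks(i, j) - 1] += 1.0; ++tokens; }
  std::vector<double> cum(n_nodes);
  double tot = 0.0;
  for (int v = 0; v < n_nodes; ++v) { tot += std::pow(cnt[v], 0.75); cum[v] = tot; }
  if (tot <= 0.0) stop("empty walk corpus");
  auto sample_noise = [&]() {
    double r = unif(rng) * tot;
    int lo = 0, hi = n_nodes - 1;
    while (lo < hi) { int mid = (lo + hi) / 2; if (cum[mid] < r) lo = mid + 1; else hi = mid; }
    return lo;
  };

  const double total_pairs =
      std::max(1.0, static_cast<double>(tokens) * epochs * 2.0 * window);
  double processed = 0.0;
  std::vector<double> grad_in(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = 0; i < nwalk; ++i) {
      for (int j = 0; j < len; ++j) {
        const int w = walks(i, j);
        if (w <= 0) continue;
        const double *null_ = nullptr; (void)null_;
        for (int off = -window; off <= window; ++off) {
          if (off == 0) continue;
          const int jc = j + off;
          if (jc < 0 || jc >= len) continue;
          const int c = walks(i, jc);
          processed += 1.0;
          if (c <= 0) continue;
          const double lr =
              lr0 * std::max(1e-4, 1.0 - processed / total_pairs);
          double *iw = vin.data() + static_cast<size_t>(w - 1) * dim;
          std::fill(grad_in.begin(), grad_in.end(), 0.0);
          for (int s = 0; s <= negative; ++s) {
            int target; double label;
            if (s == 0) { target = c - 1; label = 1.0; }
            else {
              target = sample_noise();
              if (target == c - 1) continue;
              label = 0.0;
            }
            double *ov = vout.data() + static_cast<size_t>(target) * dim;
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += iw[d] * ov[d];
            const double g = (label - fast_sigmoid(dot)) * lr;
            for (int d = 0; d < dim; ++d) {
              grad_in[d] += g * ov[d];
              ov[d] += g * iw[d];
            }
          }
          for (int d = 0; d < dim; ++d) iw[d] += grad_in[d];
        }
      }
    }
  }

  NumericMatrix out(n_nodes, dim);
  for (int v = 0; v < n_nodes; ++v)
    for (int d = 0; d < dim; ++d)
      out(v, d) = vin[static_cast<size_t>(v) * dim + d];
  return out;
}
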