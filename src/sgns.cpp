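#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Skip-gram with negative sampling, single worker, trained with SGD on
// float vectors (the usual word2vec layout: input vectors syn0, output
// vectors syn1, only syn0 exported). All randomness is drawn from R's
// stream, so results are reproducible under set.seed().

// precomputed sigmoid table over [-MAX_EXP, MAX_EXP], the standard
// word2vec speed trick; values outside the range saturate
#define EXP_TABLE_SIZE 4096
#define MAX_EXP 6.0f
static std::vector<float> exp_table;
static void init_exp_table() {
  if (!exp_table.empty()) return;
  exp_table.resize(EXP_TABLE_SIZE + 1);
  for (int i = 0; i <= EXP_TABLE_SIZE; ++i) {
    const double x = ((double)i / EXP_TABLE_SIZE * 2.0 - 1.0) * MAX_EXP;
    exp_table[i] = (float)(1.0 / (1.0 + std::exp(-x)));
  }
}
static inline float sigmoidf(float x) {
  if (x >= MAX_EXP) return exp_table[EXP_TABLE_SIZE];
  if (x <= -MAX_EXP) return exp_table[0];
  return exp_table[(int)((x / MAX_EXP + 1.0f) * (EXP_TABLE_SIZE / 2))];
}

// corpus: list of integer vectors of 0-based vocabulary indices.
// Returns the input vectors (vocab x dim) and the mean per-epoch training
// loss, estimated on every 16th context pair.
// [[Rcpp::export]]
List cpp_sgns_train(List corpus, int vocab_size, int dim, int window,
                    int negative, int epochs, double lr0) {
  init_exp_table();
  const int V = vocab_size;

  // unigram counts and the noise distribution (unigram ^ 3/4), as a
  // cumulative table sampled by binary search
  std::vector<double> counts(V, 0.0);
  long long total_tokens = 0;
  const int nsent = corpus.size();
  std::vector<IntegerVector> sents;
  sents.reserve(nsent);
  for (int i = 0; i < nsent; ++i) {
    IntegerVector s = corpus[i];
    for (int j = 0; j < s.size(); ++j) counts[s[j]] += 1.0;
    total_tokens += s.size();
    sents.push_back(s);
  }
  std::vector<double> noise_cdf(V);
  double acc = 0.0;
  for (int v = 0; v < V; ++v) {
    acc += std::pow(counts[v], 0.75);
    noise_cdf[v] = acc;
  }
  const double noise_total = acc;

  // init: syn0 uniform in (-0.5/dim, 0.5/dim), syn1 zero
  std::vector<float> syn0((size_t)V * dim), syn1((size_t)V * dim, 0.0f);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (float)((unif_rand() - 0.5) / dim);

  std::vector<float> neu1e(dim);
  NumericVector epoch_loss(epochs);
  const double lr_floor = lr0 * 1e-4;
  const long long sched = (long long)total_tokens * epochs + 1;
  long long processed = 0, pair_counter = 0;
  double lr = lr0;

  for (int ep = 0; ep < epochs; ++ep) {
    double loss_sum = 0.0;
    long long loss_n = 0;
    for (int si = 0; si < nsent; ++si) {
      const IntegerVector& s = sents[si];
      const int T = s.size();
      for (int t = 0; t < T; ++t) {
        // linear learning-rate decay over all epochs
        lr = lr0 * (1.0 - (double)processed / (double)sched);
        if (lr < lr_floor) lr = lr_floor;
        ++processed;
        // distance downsampling: reduced window b drawn uniformly in 1..window
        int b = 1 + (int)(unif_rand() * window);
        if (b > window) b = window;
        const int center = s[t];
        float* vin = syn0.data() + (size_t)center * dim;
        for (int j = -b; j <= b; ++j) {
          if (j == 0) continue;
          const int tj = t + j;
          if (tj < 0 || tj >= T) continue;
          const int context = s[tj];
          const bool track = ((pair_counter++ & 15LL) == 0);
          std::fill(neu1e.begin(), neu1e.end(), 0.0f);
          for (int neg = 0; neg <= negative; ++neg) {
            int target;
            float label;
            if (neg == 0) {
              target = context;
              label = 1.0f;
            } else {
              target = -1;
              for (int tries = 0; tries < 16; ++tries) {
                const double r = unif_rand() * noise_total;
                int cand = (int)(std::lower_bound(noise_cdf.begin(), noise_cdf.end(), r)
                                 - noise_cdf.begin());
                if (cand >= V) cand = V - 1;
                if (cand != context) { target = cand; break; }
              }
              if (target < 0) continue; // degenerate vocabulary: skip the draw
              label = 0.0f;
            }
            float* vout = syn1.data() + (size_t)target * dim;
            // dot product with four partial sums to break the serial
            // floating-point dependency chain
            float f0 = 0.0f, f1 = 0.0f, f2 = 0.0f, f3 = 0.0f;
            int d = 0;
            for (; d + 3 < dim; d += 4) {
              f0 += vin[d] * vout[d];
              f1 += vin[d + 1] * vout[d + 1];
              f2 += vin[d + 2] * vout[d + 2];
              f3 += vin[d + 3] * vout[d + 3];
            }
            float f = (f0 + f1) + (f2 + f3);
            for (; d < dim; ++d) f += vin[d] * vout[d];
            const float sg = sigmoidf(f);
            const float g = (label - sg) * (float)lr;
            if (track) {
              const float pr = (label > 0.5f) ? sg : (1.0f - sg);
              loss_sum += -std::log((double)pr + 1e-10);
            }
            float* __restrict__ ne = neu1e.data();
            const float* __restrict__ vo = vout;
            for (int d2 = 0; d2 < dim; ++d2) ne[d2] += g * vo[d2];
            const float* __restrict__ vi = vin;
            float* __restrict__ vo2 = vout;
            for (int d2 = 0; d2 < dim; ++d2) vo2[d2] += g * vi[d2];
          }
          if (track) ++loss_n;
          {
            float* __restrict__ vi = vin;
            const float* __restrict__ ne = neu1e.data();
            for (int d2 = 0; d2 < dim; ++d2) vi[d2] += ne[d2];
          }
        }
      }
    }
    epoch_loss[ep] = loss_n > 0 ? loss_sum / (double)loss_n : NA_REAL;
  }

  NumericMatrix vectors(V, dim);
  for (int v = 0; v < V; ++v)
    for (int d = 0; d < dim; ++d)
      vectors(v, d) = (double)syn0[(size_t)v * dim + d];
  return List::create(_["vectors"] = vectors, _["epoch_loss"] = epoch_loss);
}
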