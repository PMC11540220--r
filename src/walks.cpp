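#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Walk strategies operate on a CSR adjacency: adj holds the 0-based
// neighbours of node u in positions [off[u], off[u+1]), sorted ascending
// (sortedness is required by the node2vec previous-node membership test).

enum Strategy { STRAT_RW = 0, STRAT_DG = 1, STRAT_ID = 2, STRAT_TSAW = 3, STRAT_N2V = 4 };

static inline bool is_adjacent(const int* adj, const int* off, int u, int v) {
  return std::binary_search(adj + off[u], adj + off[u + 1], v);
}

// Unnormalized transition weights tau_{uv} for every neighbour of cur,
// written into w (length >= deg(cur)); returns the normalizer Z_u.
static double neighbor_weights(int strat, const int* adj, const int* off,
                               int cur, int prev, const std::vector<int>& visits,
                               double lambda, double p, double q, double* w) {
  const int s = off[cur], e = off[cur + 1];
  double Z = 0.0;
  for (int i = s; i < e; ++i) {
    const int v = adj[i];
    double t;
    switch (strat) {
    case STRAT_RW: t = 1.0; break;
    case STRAT_DG: t = (double)(off[v + 1] - off[v]); break;
    case STRAT_ID: t = 1.0 / (double)(off[v + 1] - off[v]); break;
    case STRAT_TSAW: t = std::exp(-lambda * (double)visits[v]); break;
    default: // node2vec second-order rule; first step (prev < 0) is uniform
      if (prev < 0) t = 1.0;
      else if (v == prev) t = 1.0 / p;
      else if (is_adjacent(adj, off, prev, v)) t = 1.0;
      else t = 1.0 / q;
    }
    w[i - s] = t;
    Z += t;
  }
  return Z;
}

// Inverse-CDF draw over the weight vector (one shared R random stream).
static int draw_neighbor(const int* adj, int s, int deg, const double* w, double Z) {
  const double u = unif_rand() * Z;
  double c = 0.0;
  for (int i = 0; i < deg; ++i) {
    c += w[i];
    if (u <= c) return adj[s + i];
  }
  return adj[s + deg - 1]; // guard against rounding at the top of the CDF
}

// Generate one walk per entry of `starts`, each of at most `alpha` nodes,
// truncating at neighbourless nodes. TSAW visit counts are per-walk, with
// the start node counted as visited once at initialization.
// [[Rcpp::export]]
List cpp_generate_walks(IntegerVector adj_, IntegerVector off_, IntegerVector starts,
                        int alpha, int strategy, double lambda, double p, double q) {
  const int* adj = adj_.begin();
  const int* off = off_.begin();
  const int n = off_.size() - 1;
  const int nwalks = starts.size();

  int maxdeg = 0;
  for (int u = 0; u < n; ++u) maxdeg = std::max(maxdeg, off[u + 1] - off[u]);
  std::vector<double> w(std::max(maxdeg, 1));
  std::vector<int> visits(strategy == STRAT_TSAW ? n : 0, 0);
  std::vector<int> touched;

  List out(nwalks);
  std::vector<int> seq;
  seq.reserve(alpha);

  for (int k = 0; k < nwalks; ++k) {
    int cur = starts[k], prev = -1;
    seq.clear();
    seq.push_back(cur);
    if (strategy == STRAT_TSAW) {
      for (int t : touched) visits[t] = 0;
      touched.clear();
      visits[cur] = 1;
      touched.push_back(cur);
    }
    for (int step = 1; step < alpha; ++step) {
      const int deg = off[cur + 1] - off[cur];
      if (deg == 0) break; // dead end: keep the truncated walk
      const double Z = neighbor_weights(strategy, adj, off, cur, prev, visits,
                                        lambda, p, q, w.data());
      const int nxt = draw_neighbor(adj, off[cur], deg, w.data(), Z);
      if (strategy == STRAT_TSAW) {
        if (visits[nxt] == 0) touched.push_back(nxt);
        visits[nxt] += 1;
      }
      prev = cur;
      cur = nxt;
      seq.push_back(cur);
    }
    IntegerVector sv(seq.begin(), seq.end());
    out[k] = sv;
  }
  return out;
}

// Repeatedly sample the next node from one fixed walk state; returns per-node
// counts. Exercises the same weight and inverse-CDF code path as the walker.
// [[Rcpp::export]]
IntegerVector cpp_sample_steps(IntegerVector adj_, IntegerVector off_, int current,
                               int prev, IntegerVector visit_counts, int nsteps,
                               int strategy, double lambda, double p, double q) {
  const int* adj = adj_.begin();
  const int* off = off_.begin();
  const int n = off_.size() - 1;
  const int deg = off[current + 1] - off[current];
  if (deg == 0) stop("current node has no neighbours");
  std::vector<int> visits(visit_counts.begin(), visit_counts.end());
  std::vector<double> w(deg);
  IntegerVector counts(n);
  for (int i = 0; i < nsteps; ++i) {
    const double Z = neighbor_weights(strategy, adj, off, current, prev, visits,
                                      lambda, p, q, w.data());
    counts[draw_neighbor(adj, off[current], deg, w.data(), Z)] += 1;
  }
  return counts;
}
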