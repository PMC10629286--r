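// Graph embedding kernels: second-order biased random walks, skip-gram with
// negative sampling over a walk corpus, and personalized-PageRank
// noise-contrastive embedding. All randomness comes from a caller-supplied
// seed through a private mt19937 engine, so results are reproducible and
// independent of R's RNG state.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// binary search for `target` among the (sorted) neighbours of `node`
static inline bool has_edge(const std::vector<int>& adj,
                            const std::vector<int>& off,
                            int node, int target) {
  const int* lo = adj.data() + off[node];
  const int* hi = adj.data() + off[node + 1];
  return std::binary_search(lo, hi, target);
}

static inline int sample_discrete(const std::vector<double>& w, double total,
                                  std::mt19937& rng) {
  std::uniform_real_distribution<double> unif(0.0, total);
  double r = unif(rng);
  double acc = 0.0;
  for (size_t i = 0; i < w.size(); ++i) {
    acc += w[i];
    if (r <= acc) return (int)i;
  }
  return (int)w.size() - 1;
}

// [[Rcpp::export]]
IntegerMatrix cpp_node2vec_walks(IntegerVector offsets_, IntegerVector adj_,
                                 NumericVector wts_, int walk_length,
                                 int walks_per_node, double return_p,
                                 double inout_q, int seed, bool weighted) {
  const int n = offsets_.size() - 1;
  std::vector<int> off(offsets_.begin(), offsets_.end());
  std::vector<int> adj(adj_.begin(), adj_.end());
  std::vector<double> wts(wts_.begin(), wts_.end());
  std::mt19937 rng((unsigned)seed);

  IntegerMatrix walks(n * walks_per_node, walk_length);
  std::fill(walks.begin(), walks.end(), NA_INTEGER);
  std::vector<double> bias;

  int row = 0;
  for (int w = 0; w < walks_per_node; ++w) {
    for (int v = 0; v < n; ++v, ++row) {
      walks(row, 0) = v + 1;  // 1-based for R
      int prev = -1, cur = v;
      for (int step = 1; step < walk_length; ++step) {
        int deg = off[cur + 1] - off[cur];
        if (deg == 0) break;  // isolated or dead end: truncated walk
        bias.assign(deg, 0.0);
        double total = 0.0;
        for (int k = 0; k < deg; ++k) {
          int nb = adj[off[cur] + k];
          double b = weighted ? wts[off[cur] + k] : 1.0;
          if (prev >= 0) {
            if (nb == prev) b /= return_p;
            else if (!has_edge(adj, off, prev, nb)) b /= inout_q;
            // common neighbour of prev and cur keeps factor 1
          }
          bias[k] = b;
          total += b;
        }
        int pick = sample_discrete(bias, total, rng);
        prev = cur;
        cur = adj[off[cur] + pick];
        walks(row, step) = cur + 1;
      }
    }
  }
  return walks;
}

static inline double fast_sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// [[Rcpp::export]]
NumericMatrix cpp_sgns(IntegerMatrix walks, int n_nodes, int dim, int window,
                       int negatives, int epochs, double lr, int seed) {
  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> unif01(0.0, 1.0);

  // unigram^0.75 negative-sampling table from corpus frequencies
  std::vector<double> cnt(n_nodes, 0.0);
  long total_tokens = 0;
  for (int i = 0; i < walks.nrow(); ++i)
    for (int j = 0; j < walks.ncol(); ++j)
      if (walks(i, j) != NA_INTEGER) { cnt[walks(i, j) - 1] += 1.0; ++total_tokens; }
  std::vector<double> cum(n_nodes);
  double z = 0.0;
  for (int v = 0; v < n_nodes; ++v) { z += std::pow(cnt[v], 0.75); cum[v] = z; }

  auto sample_neg = [&]() {
    double r = unif01(rng) * z;
    return (int)(std::lower_bound(cum.begin(), cum.end(), r) - cum.begin());
  };

  std::vector<double> syn0((size_t)n_nodes * dim), syn1((size_t)n_nodes * dim, 0.0);
  for (auto& x : syn0) x = (unif01(rng) - 0.5) / dim;

  std::vector<double> grad(dim);
  long pair_budget = (long)total_tokens * epochs;
  long done = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = 0; i < walks.nrow(); ++i) {
      for (int j = 0; j < walks.ncol(); ++j) {
        if (walks(i, j) == NA_INTEGER) break;
        int center = walks(i, j) - 1;
        double alpha = lr * (1.0 - (double)done / (pair_budget + 1));
        if (alpha < lr * 1e-4) alpha = lr * 1e-4;
        ++done;
        int b = (int)(unif01(rng) * window);  // dynamic window, word2vec style
        for (int k = j - window + b; k <= j + window - b; ++k) {
          if (k == j || k < 0 || k >= walks.ncol()) continue;
          if (walks(i, k) == NA_INTEGER) continue;
          int ctx = walks(i, k) - 1;
          double* v0 = syn0.data() + (size_t)center * dim;
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int neg = 0; neg <= negatives; ++neg) {
            int target; double label;
            if (neg == 0) { target = ctx; label = 1.0; }
            else {
              target = sample_neg();
              if (target == ctx) continue;
              label = 0.0;
            }
            double* v1 = syn1.data() + (size_t)target * dim;
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += v0[d] * v1[d];
            double g = (label - fast_sigmoid(dot)) * alpha;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * v1[d];
              v1[d] += g * v0[d];
            }
          }
          for (int d = 0; d < dim; ++d) v0[d] += grad[d];
        }
      }
    }
  }
  NumericMatrix out(n_nodes, dim);
  for (int v = 0; v < n_nodes; ++v)
    for (int d = 0; d < dim; ++d) out(v, d) = syn0[(size_t)v * dim + d];
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_ppr_nce(IntegerVector offsets_, IntegerVector adj_,
                          NumericVector wts_, int n_nodes, int dim,
                          double alpha, int negatives, int samples_per_node,
                          int epochs, double lr, int seed, bool weighted) {
  std::vector<int> off(offsets_.begin(), offsets_.end());
  std::vector<int> adj(adj_.begin(), adj_.end());
  std::vector<double> wts(wts_.begin(), wts_.end());
  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> unif01(0.0, 1.0);
  std::uniform_int_distribution<int> unif_node(0, n_nodes - 1);

  std::vector<double> W((size_t)n_nodes * dim);
  for (auto& x : W) x = (unif01(rng) - 0.5) / dim;
  std::vector<double> bias, grad(dim);

  // one weighted first-order step from `cur`
  auto step_from = [&](int cur) -> int {
    int deg = off[cur + 1] - off[cur];
    if (deg == 0) return -1;
    if (!weighted) {
      std::uniform_int_distribution<int> pick(0, deg - 1);
      return adj[off[cur] + pick(rng)];
    }
    double total = 0.0;
    bias.assign(deg, 0.0);
    for (int k = 0; k < deg; ++k) { bias[k] = wts[off[cur] + k]; total += bias[k]; }
    return adj[off[cur] + sample_discrete(bias, total, rng)];
  };

  long total_updates = (long)n_nodes * samples_per_node * epochs;
  long done = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < samples_per_node; ++s) {
      for (int u = 0; u < n_nodes; ++u) {
        double a = lr * (1.0 - (double)done / (total_updates + 1));
        if (a < lr * 1e-4) a = lr * 1e-4;
        ++done;
        // positive ~ personalized PageRank from u: take one step, then keep
        // walking with probability alpha (damping), stop with 1 - alpha
        int v = step_from(u);
        if (v < 0) continue;
        while (unif01(rng) < alpha) {
          int nxt = step_from(v);
          if (nxt < 0) break;
          v = nxt;
        }
        double* wu = W.data() + (size_t)u * dim;
        std::fill(grad.begin(), grad.end(), 0.0);
        for (int neg = 0; neg <= negatives; ++neg) {
          int target; double label;
          if (neg == 0) { target = v; label = 1.0; }
          else { target = unif_node(rng); if (target == u) continue; label = 0.0; }
          double* wt = W.data() + (size_t)target * dim;
          double dot = 0.0;
          for (int d = 0; d < dim; ++d) dot += wu[d] * wt[d];
          double g = (label - fast_sigmoid(dot)) * a;
          for (int d = 0; d < dim; ++d) {
            grad[d] += g * wt[d];
            wt[d] += g * wu[d];
          }
        }
        for (int d = 0; d < dim; ++d) wu[d] += grad[d];
      }
    }
  }
  NumericMatrix out(n_nodes, dim);
  for (int v = 0; v < n_nodes; ++v)
    for (int d = 0; d < dim; ++d) out(v, d) = W[(size_t)v * dim + d];
  return out;
}
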