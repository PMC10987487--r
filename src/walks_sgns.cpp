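// Random-walk generation and skip-gram-with-negative-sampling training.
// Uses R's RNG throughout, so results are reproducible via set.seed().
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline int unif_index(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

static inline bool is_neighbor(const IntegerVector& indptr,
                               const IntegerVector& indices,
                               int node, int query) {
  int lo = indptr[node], hi = indptr[node + 1];
  return std::binary_search(indices.begin() + lo, indices.begin() + hi, query);
}

// Second-order (node2vec-style) random walks over a CSR adjacency with
// sorted neighbor lists; p is the return parameter, q the in-out
// parameter (p = q = 1 gives plain uniform walks). All ids 0-based.
// [[Rcpp::export]]
IntegerMatrix random_walks_cpp(IntegerVector indptr, IntegerVector indices,
                               IntegerVector starts, int walk_length,
                               double p, double q) {
  int nw = starts.size();
  IntegerMatrix walks(nw, walk_length);
  bool unbiased = (p == 1.0 && q == 1.0);
  double wmax = std::max(1.0, std::max(1.0 / p, 1.0 / q));
  for (int w = 0; w < nw; ++w) {
    int cur = starts[w];
    int prev = -1;
    walks(w, 0) = cur;
    for (int t = 1; t < walk_length; ++t) {
      int beg = indptr[cur], deg = indptr[cur + 1] - beg;
      if (deg == 0) { walks(w, t) = cur; prev = cur; continue; }
      int nxt;
      if (unbiased || prev < 0 || deg == 1) {
        nxt = indices[beg + unif_index(deg)];
      } else {
        // rejection sampling of the biased transition
        for (;;) {
          int y = indices[beg + unif_index(deg)];
          double wgt = (y == prev) ? 1.0 / p
                       : (is_neighbor(indptr, indices, prev, y) ? 1.0
                                                                : 1.0 / q);
          if (unif_rand() * wmax <= wgt) { nxt = y; break; }
        }
      }
      walks(w, t) = nxt;
      prev = cur;
      cur = nxt;
    }
  }
  return walks;
}

// Skip-gram with negative sampling over precomputed (center, context)
// pairs, plain SGD with linearly decaying learning rate - the word2vec
// update. unigram_cdf is the cumulative noise distribution over nodes.
// Returns the center-embedding matrix (n_nodes x dim).
// [[Rcpp::export]]
NumericMatrix sgns_train_cpp(IntegerVector ctr, IntegerVector ctx,
                             int n_nodes, int dim, int epochs,
                             double lr0, int neg,
                             NumericVector unigram_cdf) {
  R_xlen_t np = ctr.size();
  std::vector<double> U((size_t)n_nodes * dim), V((size_t)n_nodes * dim, 0.0);
  for (size_t i = 0; i < U.size(); ++i) U[i] = (unif_rand() - 0.5) / dim;
  std::vector<double> work(dim);
  double total = (double)np * epochs;
  double done = 0.0;
  const double* cdf = unigram_cdf.begin();
  for (int ep = 0; ep < epochs; ++ep) {
    for (R_xlen_t s = 0; s < np; ++s, done += 1.0) {
      double lr = lr0 * (1.0 - done / (total + 1.0));
      if (lr < lr0 * 1e-4) lr = lr0 * 1e-4;
      int u = ctr[s];
      double* uu = &U[(size_t)u * dim];
      std::fill(work.begin(), work.end(), 0.0);
      for (int k = 0; k <= neg; ++k) {
        int target;
        double label;
        if (k == 0) { target = ctx[s]; label = 1.0; }
        else {
          double r = unif_rand();
          target = (int)(std::lower_bound(cdf, cdf + n_nodes, r) - cdf);
          if (target >= n_nodes) target = n_nodes - 1;
          if (target == ctx[s]) continue;
          label = 0.0;
        }
        double* vv = &V[(size_t)target * dim];
        double dot = 0.0;
        for (int d = 0; d < dim; ++d) dot += uu[d] * vv[d];
        double g = (1.0 / (1.0 + std::exp(-dot)) - label) * lr;
        for (int d = 0; d < dim; ++d) {
          work[d] += g * vv[d];
          vv[d] -= g * uu[d];
        }
      }
      for (int d = 0; d < dim; ++d) uu[d] -= work[d];
    }
  }
  NumericMatrix out(n_nodes, dim);
  for (int i = 0; i < n_nodes; ++i)
    for (int d = 0; d < dim; ++d) out(i, d) = U[(size_t)i * dim + d];
  return out;
}
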