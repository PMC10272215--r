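#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

// Heterogeneous skip-gram with negative sampling over a walk corpus.
//
// Standard SGNS (input vectors syn0, output vectors syn1, logistic loss,
// linearly decaying learning rate) with one modification for typed graphs:
// negative samples for a (center, context) pair are drawn from the unigram
// distribution (raised to 3/4) restricted to nodes of the CONTEXT node's
// type, so each type competes only within itself and embeddings remain
// aware of the node-type structure.
//
// Single-threaded and driven by its own PRNG: a fixed seed yields an
// identical embedding matrix on every run.

// [[Rcpp::export(name = ".cpp_train_sgns")]]
NumericMatrix cpp_train_sgns(IntegerMatrix walks, IntegerVector node_type,
                             int n_nodes, int dim, int window,
                             int negatives, int epochs,
                             double alpha0, double seed) {
  const int n_walks = walks.nrow(), wlen = walks.ncol();
  const int n_types = *std::max_element(node_type.begin(), node_type.end()) + 1;

  // unigram counts from the corpus
  std::vector<double> cnt(n_nodes, 0.0);
  for (int i = 0; i < n_walks; ++i)
    for (int j = 0; j < wlen; ++j)
      if (walks(i, j) >= 0) cnt[walks(i, j)] += 1.0;

  // per-type cumulative tables over count^0.75
  std::vector<std::vector<int>> pool(n_types);
  std::vector<std::vector<double>> cum(n_types);
  for (int v = 0; v < n_nodes; ++v) {
    if (cnt[v] > 0) pool[node_type[v]].push_back(v);
  }
  for (int t = 0; t < n_types; ++t) {
    double acc = 0.0;
    cum[t].reserve(pool[t].size());
    for (size_t k = 0; k < pool[t].size(); ++k) {
      acc += std::pow(cnt[pool[t][k]], 0.75);
      cum[t].push_back(acc);
    }
  }
  if (negatives > 0) {
    for (int t = 0; t < n_types; ++t) {
      if (!pool[t].empty() && pool[t].size() < 2)
        stop("negative pool too small: a node type present in the corpus has a single node");
    }
  }

  uint64_t st = (uint64_t)seed;
  st = splitmix64(st) + 0xA0761D6478BD642FULL;
  XorShift rng(st);

  // init: syn0 uniform in (-0.5, 0.5)/dim, syn1 zero (word2vec convention)
  std::vector<float> syn0((size_t)n_nodes * dim), syn1((size_t)n_nodes * dim, 0.0f);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (float)((rng.unif() - 0.5) / dim);

  // count pair updates for the learning-rate schedule
  long long total_pairs = 0;
  std::vector<int> valid_len(n_walks);
  for (int i = 0; i < n_walks; ++i) {
    int L = 0;
    while (L < wlen && walks(i, L) >= 0) ++L;
    valid_len[i] = L;
    for (int c = 0; c < L; ++c) {
      int lo = std::max(0, c - window), hi = std::min(L - 1, c + window);
      total_pairs += (hi - lo); // excludes the center itself
    }
  }
  total_pairs *= epochs;
  if (total_pairs == 0) stop("empty corpus");

  std::vector<float> neu1e(dim);
  long long done = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = 0; i < n_walks; ++i) {
      const int L = valid_len[i];
      for (int c = 0; c < L; ++c) {
        const int center = walks(i, c);
        const int lo = std::max(0, c - window), hi = std::min(L - 1, c + window);
        for (int j = lo; j <= hi; ++j) {
          if (j == c) continue;
          const int context = walks(i, j);
          const double lr = alpha0 *
            std::max(1.0 - (double)done / (double)total_pairs, 1e-4);
          ++done;
          float *v0 = &syn0[(size_t)center * dim];
          std::fill(neu1e.begin(), neu1e.end(), 0.0f);
          const int ttype = node_type[context];
          const std::vector<int> &tp = pool[ttype];
          const std::vector<double> &tc = cum[ttype];
          const double ctot = tc.back();
          for (int d = 0; d <= negatives; ++d) {
            int target; double label;
            if (d == 0) { target = context; label = 1.0; }
            else {
              target = context;
              for (int tries = 0; tries < 16 && target == context; ++tries) {
                const double r = rng.unif() * ctot;
                size_t k = std::lower_bound(tc.begin(), tc.end(), r) - tc.begin();
                if (k >= tp.size()) k = tp.size() - 1;
                target = tp[k];
              }
              if (target == context) continue;
              label = 0.0;
            }
            float *v1 = &syn1[(size_t)target * dim];
            // 4-way unrolled dot and update (dim is typically a multiple
            // of 4; a scalar tail covers the rest)
            float f0 = 0.f, f1 = 0.f, f2 = 0.f, f3 = 0.f;
            int k = 0;
            for (; k + 3 < dim; k += 4) {
              f0 += v0[k] * v1[k];
              f1 += v0[k + 1] * v1[k + 1];
              f2 += v0[k + 2] * v1[k + 2];
              f3 += v0[k + 3] * v1[k + 3];
            }
            double f = (double)(f0 + f1) + (double)(f2 + f3);
            for (; k < dim; ++k) f += (double)v0[k] * v1[k];
            const float g = (float)((label - 1.0 / (1.0 + std::exp(-f))) * lr);
            k = 0;
            for (; k + 3 < dim; k += 4) {
              neu1e[k] += g * v1[k];
              neu1e[k + 1] += g * v1[k + 1];
              neu1e[k + 2] += g * v1[k + 2];
              neu1e[k + 3] += g * v1[k + 3];
              v1[k] += g * v0[k];
              v1[k + 1] += g * v0[k + 1];
              v1[k + 2] += g * v0[k + 2];
              v1[k + 3] += g * v0[k + 3];
            }
            for (; k < dim; ++k) {
              neu1e[k] += g * v1[k];
              v1[k] += g * v0[k];
            }
          }
          for (int k = 0; k < dim; ++k) v0[k] += neu1e[k];
        }
      }
    }
  }

  NumericMatrix out(n_nodes, dim);
  for (int v = 0; v < n_nodes; ++v)
    for (int k = 0; k < dim; ++k)
      out(v, k) = syn0[(size_t)v * dim + k];
  return out;
}
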