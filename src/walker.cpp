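#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include "rng.h"

using namespace Rcpp;

// Teleport-guided, edge-type- and node2vec-biased random walk sampler.
//
// Graph is passed as 0-based CSR over both edge directions, entries sorted
// by neighbour index within each node block (binary-searchable). Teleport
// rows (semantic similarity) are a second CSR, non-empty only for
// teleport-eligible nodes. The per-step law matches step_distribution() in
// R/walker.R exactly:
//
//   * at a teleport-eligible node with a non-empty similarity row, teleport
//     with probability tau, landing proportional to the similarity row;
//   * otherwise traverse: neighbour n gets unnormalised weight
//     w_vn * M[incoming_type, type(v,n)] * alpha_pq(n, prev),
//     where alpha = 1/p if n == prev, 1 if n adjacent to prev, 1/q else;
//     the M factor and alpha are dropped at walk starts and right after a
//     teleport (no incoming edge type, no previous node);
//   * a node with no graph neighbours but a similarity row teleports with
//     probability 1.
//
// Each walk consumes its own substream seeded from (seed, start, walk_index),
// so corpora are reproducible and independent of walk scheduling order.

static inline bool adjacent_to(const IntegerVector &ptr, const IntegerVector &nbr,
                               int u, int x) {
  int lo = ptr[u], hi = ptr[u + 1];
  return std::binary_search(nbr.begin() + lo, nbr.begin() + hi, x);
}

// [[Rcpp::export(name = ".cpp_sample_walks")]]
List cpp_sample_walks(IntegerVector adj_ptr, IntegerVector adj_nbr,
                      IntegerVector adj_et, NumericVector adj_w,
                      NumericMatrix M,
                      IntegerVector tele_ptr, IntegerVector tele_nbr,
                      NumericVector tele_w,
                      double tau, double p, double q,
                      IntegerVector start_nodes,
                      int num_walks, int walk_len,
                      double seed, bool use_teleport) {
  const int n_start = start_nodes.size();
  const int n_walks = n_start * num_walks;
  const int n_steps = walk_len - 1;
  IntegerMatrix walks(n_walks, walk_len);
  IntegerMatrix actions(n_walks, std::max(n_steps, 1)); // 0 traverse, 1 teleport, -1 unused
  IntegerMatrix etypes(n_walks, std::max(n_steps, 1));  // edge-type idx, -1 none
  std::fill(actions.begin(), actions.end(), -1);
  std::fill(etypes.begin(), etypes.end(), -1);
  std::vector<double> wbuf;

  int row = 0;
  for (int si = 0; si < n_start; ++si) {
    const int start = start_nodes[si];
    for (int wi = 0; wi < num_walks; ++wi, ++row) {
      uint64_t st = (uint64_t)seed;
      st = splitmix64(st) + 0x9E3779B97f4A7C15ULL * (uint64_t)(start + 1);
      st = splitmix64(st) + 0x632BE59BD9B4E019ULL * (uint64_t)(wi + 1);
      XorShift rng(st);

      int curr = start, prev = -1, in_et = -1;
      walks(row, 0) = curr;
      for (int s = 0; s < n_steps; ++s) {
        const int a0 = adj_ptr[curr], a1 = adj_ptr[curr + 1];
        const int deg = a1 - a0;
        const int t0 = tele_ptr[curr], t1 = tele_ptr[curr + 1];
        const int tdeg = use_teleport ? (t1 - t0) : 0;
        double tau_eff = (tdeg > 0) ? tau : 0.0;
        if (deg == 0) {
          if (tdeg == 0) { // dead end: truncate (walk kept, padded with -1)
            for (int r2 = s; r2 < n_steps; ++r2) walks(row, r2 + 1) = -1;
            break;
          }
          tau_eff = 1.0;
        }
        const double u01 = rng.unif();
        if (u01 < tau_eff) {
          // teleport: land proportional to similarity row
          double tot = 0.0;
          for (int e = t0; e < t1; ++e) tot += tele_w[e];
          double r = rng.unif() * tot, acc = 0.0;
          int pick = t1 - 1;
          for (int e = t0; e < t1; ++e) {
            acc += tele_w[e];
            if (r < acc) { pick = e; break; }
          }
          prev = -1; in_et = -1;
          curr = tele_nbr[pick];
          walks(row, s + 1) = curr;
          actions(row, s) = 1;
          etypes(row, s) = -1;
        } else {
          wbuf.resize(deg);
          double tot = 0.0;
          for (int e = a0; e < a1; ++e) {
            double w = adj_w[e];
            if (in_et >= 0) w *= M(in_et, adj_et[e]);
            if (prev >= 0) {
              const int x = adj_nbr[e];
              if (x == prev) w /= p;
              else if (!adjacent_to(adj_ptr, adj_nbr, prev, x)) w /= q;
            }
            wbuf[e - a0] = w;
            tot += w;
          }
          double r = rng.unif() * tot, acc = 0.0;
          int pick = a1 - 1;
          for (int e = a0; e < a1; ++e) {
            acc += wbuf[e - a0];
            if (r < acc) { pick = e; break; }
          }
          prev = curr; in_et = adj_et[pick];
          curr = adj_nbr[pick];
          walks(row, s + 1) = curr;
          actions(row, s) = 0;
          etypes(row, s) = in_et;
        }
      }
    }
  }
  return List::create(_["walks"] = walks, _["actions"] = actions,
                      _["etypes"] = etypes);
}
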