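#include <Rcpp.h>
#include <unordered_set>
#include <cmath>
using namespace Rcpp;

// Degree-preserving double-edge swaps on a directed edge list.
//
// One swap exchanges targets of two randomly chosen edges
// (a->b, c->d) => (a->d, c->b); candidates creating a self-loop or a
// duplicate edge are rejected and do not count as accepted swaps.
// Three stopping rules (whichever fires first):
//   - n_swaps accepted swaps (n_swaps < 0: unlimited)
//   - displace_target edges displaced from their original position
//     (displace_target < 0: disabled)
//   - stop_rejects consecutive rejections (<= 0: disabled; used by
//     latticization as its convergence rule)
// max_attempts bounds total attempts; exhaustion is flagged, not an error.
// lattice mode additionally requires a strict decrease of
// |o[a]-o[b]| + |o[c]-o[d]| where o is the node order index.
// Draws come from R's RNG stream (seed via set.seed in the caller).

static inline long long ekey(int a, int b, int n) {
  return (long long)a * (long long)n + (long long)b;
}

// [[Rcpp::export]]
List cpp_rewire(IntegerMatrix edges, int n_nodes,
                double n_swaps, double max_attempts,
                bool lattice, IntegerVector order_index,
                double stop_rejects, double displace_target) {
  const int m = edges.nrow();
  std::vector<int> src(m), dst(m);
  std::unordered_set<long long> present, orig;
  present.reserve(m * 2);
  orig.reserve(m * 2);
  for (int e = 0; e < m; ++e) {
    src[e] = edges(e, 0);
    dst[e] = edges(e, 1);
    present.insert(ekey(src[e], dst[e], n_nodes));
    orig.insert(ekey(src[e], dst[e], n_nodes));
  }
  int in_place = m;
  double accepted = 0.0, attempts = 0.0, consec_rej = 0.0;
  bool exhausted = false;

  while (true) {
    if (n_swaps >= 0 && accepted >= n_swaps) break;
    if (displace_target >= 0 && (double)(m - in_place) >= displace_target) break;
    if (stop_rejects > 0 && consec_rej >= stop_rejects) break;
    if (attempts >= max_attempts) { exhausted = true; break; }
    attempts += 1.0;
    int e1 = (int)(unif_rand() * m); if (e1 >= m) e1 = m - 1;
    int e2 = (int)(unif_rand() * m); if (e2 >= m) e2 = m - 1;
    if (e1 == e2) { consec_rej += 1.0; continue; }
    const int a = src[e1], b = dst[e1], c = src[e2], d = dst[e2];
    if (a == d || c == b) { consec_rej += 1.0; continue; }
    if (present.count(ekey(a, d, n_nodes)) ||
        present.count(ekey(c, b, n_nodes))) { consec_rej += 1.0; continue; }
    if (lattice) {
      const double before = std::fabs((double)order_index[a] - order_index[b]) +
                            std::fabs((double)order_index[c] - order_index[d]);
      const double after  = std::fabs((double)order_index[a] - order_index[d]) +
                            std::fabs((double)order_index[c] - order_index[b]);
      if (!(after < before)) { consec_rej += 1.0; continue; }
    }
    present.erase(ekey(a, b, n_nodes));
    present.erase(ekey(c, d, n_nodes));
    present.insert(ekey(a, d, n_nodes));
    present.insert(ekey(c, b, n_nodes));
    if (orig.count(ekey(a, b, n_nodes))) --in_place;
    if (orig.count(ekey(c, d, n_nodes))) --in_place;
    if (orig.count(ekey(a, d, n_nodes))) ++in_place;
    if (orig.count(ekey(c, b, n_nodes))) ++in_place;
    dst[e1] = d;
    dst[e2] = b;
    accepted += 1.0;
    consec_rej = 0.0;
  }

  IntegerMatrix out(m, 2);
  for (int e = 0; e < m; ++e) { out(e, 0) = src[e]; out(e, 1) = dst[e]; }
  return List::create(
    _["edges"] = out,
    _["accepted"] = accepted,
    _["attempts"] = attempts,
    _["exhausted"] = exhausted,
    _["displaced"] = (double)(m - in_place));
}
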