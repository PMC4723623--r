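#include <Rcpp.h>
#include <unordered_set>
using namespace Rcpp;

// Degree-preserving double-edge swaps on an undirected simple graph.
// `edges` is a 2-column matrix of 1-based node indices (a < b assumed not
// required). Each of `n_attempts` iterations picks two distinct edges and
// one of the two swap orientations at random; swaps that would create a
// self-loop or a duplicate edge are rejected (the attempt is consumed).
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List rewire_edges_cpp(IntegerMatrix edges, int n_nodes, int n_attempts) {
  int m = edges.nrow();
  std::vector<int> a(m), b(m);
  std::unordered_set<long long> present;
  present.reserve(m * 2);
  long long N = n_nodes;
  auto key = [N](int x, int y) {
    if (x > y) std::swap(x, y);
    return (long long)(x - 1) * N + y;
  };
  for (int i = 0; i < m; ++i) {
    a[i] = edges(i, 0);
    b[i] = edges(i, 1);
    present.insert(key(a[i], b[i]));
  }
  int successes = 0;
  if (m >= 2) {
    for (int it = 0; it < n_attempts; ++it) {
      int e1 = (int)(unif_rand() * m);
      int e2 = (int)(unif_rand() * m);
      if (e1 >= m) e1 = m - 1;
      if (e2 >= m) e2 = m - 1;
      if (e1 == e2) continue;
      int u1 = a[e1], v1 = b[e1], u2 = a[e2], v2 = b[e2];
      // orientation: (u1,v1),(u2,v2) -> (u1,v2),(u2,v1)  or  (u1,u2),(v1,v2)
      int x1, y1, x2, y2;
      if (unif_rand() < 0.5) {
        x1 = u1; y1 = v2; x2 = u2; y2 = v1;
      } else {
        x1 = u1; y1 = u2; x2 = v1; y2 = v2;
      }
      if (x1 == y1 || x2 == y2) continue;
      long long k1 = key(x1, y1), k2 = key(x2, y2);
      if (k1 == k2) continue;
      if (present.count(k1) || present.count(k2)) continue;
      present.erase(key(u1, v1));
      present.erase(key(u2, v2));
      present.insert(k1);
      present.insert(k2);
      a[e1] = std::min(x1, y1); b[e1] = std::max(x1, y1);
      a[e2] = std::min(x2, y2); b[e2] = std::max(x2, y2);
      ++successes;
    }
  }
  IntegerMatrix out(m, 2);
  for (int i = 0; i < m; ++i) {
    out(i, 0) = std::min(a[i], b[i]);
    out(i, 1) = std::max(a[i], b[i]);
  }
  return List::create(_["edges"] = out, _["successes"] = successes);
}
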