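#include <Rcpp.h>
#include <unordered_set>
using namespace Rcpp;

// Degree-preserving double-edge swaps on an undirected simple graph.
// Edges are given as 1-based (i, j) rows with weights; weights travel with
// the rewired edges, so the binary degree sequence and the weight multiset
// are preserved exactly. Proposals creating self-loops or multi-edges are
// rejected. Uses R's RNG.
// [[Rcpp::export(name = ".rewireEdges")]]
List rewire_edges(IntegerVector ei, IntegerVector ej, NumericVector w,
                  int n_nodes, int n_attempts) {
  const int m = ei.size();
  std::vector<int> a(ei.begin(), ei.end()), b(ej.begin(), ej.end());
  std::unordered_set<long long> present;
  present.reserve(m * 2);
  const long long NN = (long long)n_nodes + 1;
  auto key = [NN](int u, int v) {
    if (u > v) std::swap(u, v);
    return (long long)u * NN + v;
  };
  for (int e = 0; e < m; ++e) present.insert(key(a[e], b[e]));

  for (int t = 0; t < n_attempts; ++t) {
    int e1 = (int)(unif_rand() * m); if (e1 >= m) e1 = m - 1;
    int e2 = (int)(unif_rand() * m); if (e2 >= m) e2 = m - 1;
    if (e1 == e2) continue;
    int u1 = a[e1], v1 = b[e1], u2 = a[e2], v2 = b[e2];
    if (unif_rand() < 0.5) std::swap(u2, v2);  // random orientation
    // propose (u1, v2) and (u2, v1)
    if (u1 == v2 || u2 == v1) continue;
    if (u1 == u2 || v1 == v2) continue;  // would recreate an existing pair
    long long k1 = key(u1, v2), k2 = key(u2, v1);
    if (present.count(k1) || present.count(k2)) continue;
    present.erase(key(u1, v1));
    present.erase(key(u2, v2));
    present.insert(k1);
    present.insert(k2);
    a[e1] = u1; b[e1] = v2;
    a[e2] = u2; b[e2] = v1;
  }
  return List::create(_["i"] = IntegerVector(a.begin(), a.end()),
                      _["j"] = IntegerVector(b.begin(), b.end()),
                      _["w"] = w);
}
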