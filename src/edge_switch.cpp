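#include <Rcpp.h>
#include <unordered_set>
using namespace Rcpp;

// Degree-preserving double-edge-swap core for a bipartite edge list.
// Uses R's RNG (unif_rand), so set.seed() in R governs reproducibility.
// Edges are (tf, cyt) index pairs, 0-based; a proposed swap
// (t1-c1, t2-c2) -> (t1-c2, t2-c1) is rejected when it would create a
// duplicate edge or when the two edges share an endpoint.
// [[Rcpp::export]]
List edge_switch_core(IntegerVector tf, IntegerVector cyt,
                      int n_attempts, int n_cyt_levels) {
  int m = tf.size();
  std::vector<int> t(tf.begin(), tf.end());
  std::vector<int> c(cyt.begin(), cyt.end());
  std::unordered_set<long long> edges;
  edges.reserve(m * 2);
  const long long K = n_cyt_levels;
  for (int i = 0; i < m; ++i)
    edges.insert((long long)t[i] * K + c[i]);
  int accepted = 0;
  for (int it = 0; it < n_attempts; ++it) {
    int e1 = (int)(unif_rand() * m);
    int e2 = (int)(unif_rand() * m);
    if (e1 >= m) e1 = m - 1;
    if (e2 >= m) e2 = m - 1;
    if (e1 == e2) continue;
    int t1 = t[e1], c1 = c[e1], t2 = t[e2], c2 = c[e2];
    if (t1 == t2 || c1 == c2) continue;
    long long k1 = (long long)t1 * K + c2;
    long long k2 = (long long)t2 * K + c1;
    if (edges.count(k1) || edges.count(k2)) continue;
    edges.erase((long long)t1 * K + c1);
    edges.erase((long long)t2 * K + c2);
    edges.insert(k1);
    edges.insert(k2);
    c[e1] = c2;
    c[e2] = c1;
    ++accepted;
  }
  return List::create(_["tf"] = IntegerVector(t.begin(), t.end()),
                      _["cyt"] = IntegerVector(c.begin(), c.end()),
                      _["accepted"] = accepted);
}
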