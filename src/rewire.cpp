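// Degree-preserving randomization by double edge swaps, and null-ensemble
// inter-set edge counts for the permutation test. Nodes are 1-based integer
// indices. The swap loop is the hot path of the Q2 permutation test, so it
// uses a dense adjacency indicator and a local xorshift PRNG seeded from
// R's RNG (results stay reproducible via set.seed()).

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL) {}
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s;
  }
  // uniform integer in [0, n)
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

inline uint64_t seed_from_r() {
  // draw 64 seed bits from R's RNG so set.seed() controls the stream
  uint64_t hi = static_cast<uint64_t>(unif_rand() * 4294967296.0);
  uint64_t lo = static_cast<uint64_t>(unif_rand() * 4294967296.0);
  return (hi << 32) ^ lo;
}

// Attempt n_swaps double edge swaps in place. Each attempt picks two edges
// (a-b, c-d) and one of the two rewirings (a-d, c-b) or (a-c, b-d) at
// random; it is applied only if it creates no self-loop or duplicate edge,
// so the graph stays simple and every node keeps its degree.
void swap_edges(std::vector<int>& from, std::vector<int>& to,
                std::vector<uint8_t>& adj, int n_nodes, int n_swaps,
                XorShift& rng) {
  const int m = static_cast<int>(from.size());
  if (m < 2) return;
  const size_t n = static_cast<size_t>(n_nodes) + 1;
  for (int s = 0; s < n_swaps; ++s) {
    int e1 = rng.below(m), e2 = rng.below(m);
    if (e1 == e2) continue;
    int a = from[e1], b = to[e1], c = from[e2], d = to[e2];
    int na1, nb1, na2, nb2;
    if (rng.next() & 1) { na1 = a; nb1 = d; na2 = c; nb2 = b; }
    else                { na1 = a; nb1 = c; na2 = b; nb2 = d; }
    if (na1 == nb1 || na2 == nb2) continue;
    if (adj[na1 * n + nb1] || adj[na2 * n + nb2]) continue;
    if ((na1 == na2 && nb1 == nb2) || (na1 == nb2 && nb1 == na2)) continue;
    adj[a * n + b] = adj[b * n + a] = 0;
    adj[c * n + d] = adj[d * n + c] = 0;
    adj[na1 * n + nb1] = adj[nb1 * n + na1] = 1;
    adj[na2 * n + nb2] = adj[nb2 * n + na2] = 1;
    from[e1] = na1; to[e1] = nb1;
    from[e2] = na2; to[e2] = nb2;
  }
}

void fill_adj(std::vector<uint8_t>& adj, const std::vector<int>& from,
              const std::vector<int>& to, int n_nodes) {
  const size_t n = static_cast<size_t>(n_nodes) + 1;
  std::fill(adj.begin(), adj.end(), 0);
  for (size_t i = 0; i < from.size(); ++i) {
    adj[from[i] * n + to[i]] = adj[to[i] * n + from[i]] = 1;
  }
}

}  // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_rewire(IntegerVector from, IntegerVector to, int n_nodes,
                         int n_swaps) {
  const int m = from.size();
  std::vector<int> f(from.begin(), from.end()), t(to.begin(), to.end());
  std::vector<uint8_t> adj((static_cast<size_t>(n_nodes) + 1) *
                           (static_cast<size_t>(n_nodes) + 1), 0);
  fill_adj(adj, f, t, n_nodes);
  XorShift rng(seed_from_r());
  swap_edges(f, t, adj, n_nodes, n_swaps, rng);
  IntegerMatrix out(m, 2);
  for (int i = 0; i < m; ++i) { out(i, 0) = f[i]; out(i, 1) = t[i]; }
  return out;
}

// For each of n_null independent rewirings of the input graph, count the
// edges crossing each (set_a, set_b) pair. sets: list of 1-based node index
// vectors; set_pairs: k x 2 matrix of indices into sets (1-based). Returns
// a k x n_null matrix of cross-edge counts.
// [[Rcpp::export]]
NumericMatrix cpp_null_cross_counts(IntegerVector from, IntegerVector to,
                                    int n_nodes, List sets,
                                    IntegerMatrix set_pairs, int n_null,
                                    int n_swaps) {
  const int m = from.size();
  const int k = set_pairs.nrow();
  const int ns = sets.size();
  std::vector<std::vector<uint8_t>> member(
      ns, std::vector<uint8_t>(n_nodes + 1, 0));
  for (int s = 0; s < ns; ++s) {
    IntegerVector v = sets[s];
    for (int i = 0; i < v.size(); ++i) member[s][v[i]] = 1;
  }
  NumericMatrix out(k, n_null);
  std::vector<int> f0(from.begin(), from.end()), t0(to.begin(), to.end());
  std::vector<uint8_t> adj((static_cast<size_t>(n_nodes) + 1) *
                           (static_cast<size_t>(n_nodes) + 1), 0);
  XorShift rng(seed_from_r());
  std::vector<int> f, t;
  for (int r = 0; r < n_null; ++r) {
    f = f0;
    t = t0;
    fill_adj(adj, f, t, n_nodes);
    swap_edges(f, t, adj, n_nodes, n_swaps, rng);
    for (int p = 0; p < k; ++p) {
      const std::vector<uint8_t>& A = member[set_pairs(p, 0) - 1];
      const std::vector<uint8_t>& B = member[set_pairs(p, 1) - 1];
      int cnt = 0;
      for (int i = 0; i < m; ++i) {
        int u = f[i], v = t[i];
        if ((A[u] && B[v]) || (B[u] && A[v])) ++cnt;
      }
      out(p, r) = cnt;
    }
  }
  return out;
}
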