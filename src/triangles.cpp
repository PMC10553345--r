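#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Per-node triangle membership counts on a simple undirected graph.
// Endpoints are 1-based with from[k] < to[k], no duplicates, no loops
// (the canonical kgraph edge representation). Each triangle u < v < w is
// discovered once, from its edge (u, v), by intersecting the sorted
// adjacency lists above v.
// [[Rcpp::export]]
IntegerVector count_triangles_cpp(int n, IntegerVector from, IntegerVector to) {
  const R_xlen_t m = from.size();
  std::vector<int> deg(n, 0);
  for (R_xlen_t k = 0; k < m; ++k) {
    ++deg[from[k] - 1];
    ++deg[to[k] - 1];
  }
  std::vector<size_t> start(n + 1, 0);
  for (int i = 0; i < n; ++i) start[i + 1] = start[i] + deg[i];
  std::vector<int> adj(2 * (size_t)m);
  std::vector<size_t> pos(start.begin(), start.end() - 1);
  for (R_xlen_t k = 0; k < m; ++k) {
    const int u = from[k] - 1, v = to[k] - 1;
    adj[pos[u]++] = v;
    adj[pos[v]++] = u;
  }
  for (int i = 0; i < n; ++i)
    std::sort(adj.begin() + start[i], adj.begin() + start[i + 1]);

  IntegerVector tri(n, 0);
  for (R_xlen_t k = 0; k < m; ++k) {
    const int u = from[k] - 1, v = to[k] - 1; // u < v
    const int *au = adj.data() + start[u], *au_end = adj.data() + start[u + 1];
    const int *av = adj.data() + start[v], *av_end = adj.data() + start[v + 1];
    // common neighbours w with w > v close exactly one triangle here
    const int *pu = std::upper_bound(au, au_end, v);
    const int *pv = std::upper_bound(av, av_end, v);
    while (pu != au_end && pv != av_end) {
      if (*pu < *pv) {
        ++pu;
      } else if (*pv < *pu) {
        ++pv;
      } else {
        ++tri[u];
        ++tri[v];
        ++tri[*pu];
        ++pu;
        ++pv;
      }
    }
  }
  return tri;
}
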