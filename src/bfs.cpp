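// Breadth-first-search kernels for geodesic statistics on simple
// undirected graphs.  Edges arrive as 1-based endpoint vectors (i < j).

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Build a CSR adjacency structure.
static void build_adj(int n, const IntegerVector& ei, const IntegerVector& ej,
                      std::vector<int>& start, std::vector<int>& adj) {
  int m = ei.size();
  std::vector<int> deg(n, 0);
  for (int e = 0; e < m; ++e) { deg[ei[e] - 1]++; deg[ej[e] - 1]++; }
  start.assign(n + 1, 0);
  for (int v = 0; v < n; ++v) start[v + 1] = start[v] + deg[v];
  adj.assign(2 * m, 0);
  std::vector<int> pos(start.begin(), start.end() - 1);
  for (int e = 0; e < m; ++e) {
    int a = ei[e] - 1, b = ej[e] - 1;
    adj[pos[a]++] = b;
    adj[pos[b]++] = a;
  }
}

// All-sources BFS: sum of finite ordered-pair distances, count of
// reachable ordered pairs, and connected-component labels (0-based).
// [[Rcpp::export]]
List bfs_all_stats(int n, IntegerVector ei, IntegerVector ej) {
  std::vector<int> start, adj;
  build_adj(n, ei, ej, start, adj);
  std::vector<int> dist(n), queue(n);
  double dist_sum = 0, reach_ordered = 0;
  IntegerVector comp(n, -1);
  int ncomp = 0;
  for (int s = 0; s < n; ++s) {
    if (comp[s] >= 0) continue;
    comp[s] = ncomp;
    int head = 0, tail = 0;
    queue[tail++] = s;
    while (head < tail) {
      int u = queue[head++];
      for (int t = start[u]; t < start[u + 1]; ++t) {
        int v = adj[t];
        if (comp[v] < 0) { comp[v] = ncomp; queue[tail++] = v; }
      }
    }
    ncomp++;
  }
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    int head = 0, tail = 0;
    queue[tail++] = s;
    while (head < tail) {
      int u = queue[head++];
      for (int t = start[u]; t < start[u + 1]; ++t) {
        int v = adj[t];
        if (dist[v] < 0) {
          dist[v] = dist[u] + 1;
          dist_sum += dist[v];
          reach_ordered += 1;
          queue[tail++] = v;
        }
      }
    }
  }
  return List::create(_["dist_sum"] = dist_sum,
                      _["reach_ordered"] = reach_ordered,
                      _["comp"] = comp, _["ncomp"] = ncomp);
}

// Full geodesic distance matrix (Inf for unreachable pairs).
// [[Rcpp::export]]
NumericMatrix bfs_dist_matrix(int n, IntegerVector ei, IntegerVector ej) {
  std::vector<int> start, adj;
  build_adj(n, ei, ej, start, adj);
  NumericMatrix out(n, n);
  std::fill(out.begin(), out.end(), R_PosInf);
  std::vector<int> dist(n), queue(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    out(s, s) = 0;
    int head = 0, tail = 0;
    queue[tail++] = s;
    while (head < tail) {
      int u = queue[head++];
      for (int t = start[u]; t < start[u + 1]; ++t) {
        int v = adj[t];
        if (dist[v] < 0) {
          dist[v] = dist[u] + 1;
          out(s, v) = dist[v];
          queue[tail++] = v;
        }
      }
    }
  }
  return out;
}
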