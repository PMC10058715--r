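// Minimum s-t cut on a sparse directed graph via Dinic's blocking-flow
// algorithm. Used by the silhouette graph-cut: pixel-grid smoothness links
// plus terminal (data-term) links; the returned partition is the
// source/foreground side of a minimum cut.
#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

namespace {

struct Dinic {
  struct Arc { int to; double cap; int rev; };
  std::vector<std::vector<Arc> > adj;
  std::vector<int> level, iter;

  explicit Dinic(int n) : adj(n), level(n), iter(n) {}

  void add_edge(int a, int b, double cap) {
    Arc f = {b, cap, (int)adj[b].size()};
    Arc r = {a, 0.0, (int)adj[a].size()};
    adj[a].push_back(f);
    adj[b].push_back(r);
  }

  bool bfs(int s, int t) {
    std::fill(level.begin(), level.end(), -1);
    std::queue<int> q;
    level[s] = 0; q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      for (const Arc &a : adj[v])
        if (a.cap > 1e-12 && level[a.to] < 0) {
          level[a.to] = level[v] + 1;
          q.push(a.to);
        }
    }
    return level[t] >= 0;
  }

  double dfs(int v, int t, double f) {
    if (v == t) return f;
    for (int &i = iter[v]; i < (int)adj[v].size(); ++i) {
      Arc &a = adj[v][i];
      if (a.cap > 1e-12 && level[v] < level[a.to]) {
        double d = dfs(a.to, t, std::min(f, a.cap));
        if (d > 0) {
          a.cap -= d;
          adj[a.to][a.rev].cap += d;
          return d;
        }
      }
    }
    return 0.0;
  }

  double run(int s, int t) {
    double flow = 0.0;
    while (bfs(s, t)) {
      std::fill(iter.begin(), iter.end(), 0);
      double f;
      while ((f = dfs(s, t, R_PosInf)) > 0) flow += f;
    }
    return flow;
  }
};

} // namespace

// [[Rcpp::export(name = ".min_cut_source_side")]]
LogicalVector min_cut_source_side(IntegerVector from, IntegerVector to,
                                  NumericVector cap, int n_nodes,
                                  int source, int sink) {
  if (from.size() != to.size() || from.size() != cap.size())
    stop("from, to and cap must have equal length");
  Dinic d(n_nodes);
  for (int i = 0; i < from.size(); ++i) {
    if (from[i] < 1 || from[i] > n_nodes || to[i] < 1 || to[i] > n_nodes)
      stop("edge endpoint out of range");
    d.add_edge(from[i] - 1, to[i] - 1, cap[i]);
  }
  d.run(source - 1, sink - 1);
  // source side = nodes reachable from the source in the residual graph
  std::vector<char> vis(n_nodes, 0);
  std::queue<int> q;
  vis[source - 1] = 1; q.push(source - 1);
  while (!q.empty()) {
    int v = q.front(); q.pop();
    for (const Dinic::Arc &a : d.adj[v])
      if (a.cap > 1e-12 && !vis[a.to]) { vis[a.to] = 1; q.push(a.to); }
  }
  LogicalVector out(n_nodes);
  for (int i = 0; i < n_nodes; ++i) out[i] = vis[i] != 0;
  return out;
}
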