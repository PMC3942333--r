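// Minimum s-t cut via Dinic's max-flow algorithm.
//
// Used by the alpha-expansion solver: each expansion move over a pixel grid
// is a binary submodular energy, minimized exactly by one s-t cut. The
// blocking-flow DFS is iterative so augmenting paths of arbitrary length
// cannot overflow the C stack.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>

using namespace Rcpp;

namespace {

const double EPS = 1e-11;

struct Dinic {
  int n;
  std::vector<int> to, nxt, head, level, it;
  std::vector<double> cap;

  explicit Dinic(int n_) : n(n_), head(n_, -1), level(n_), it(n_) {}

  void add_arc(int u, int v, double c, double cr) {
    to.push_back(v); cap.push_back(c);
    nxt.push_back(head[u]); head[u] = (int)to.size() - 1;
    to.push_back(u); cap.push_back(cr);
    nxt.push_back(head[v]); head[v] = (int)to.size() - 1;
  }

  bool bfs(int s, int t) {
    std::fill(level.begin(), level.end(), -1);
    std::queue<int> q;
    level[s] = 0; q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int a = head[u]; a != -1; a = nxt[a]) {
        if (cap[a] > EPS && level[to[a]] < 0) {
          level[to[a]] = level[u] + 1;
          q.push(to[a]);
        }
      }
    }
    return level[t] >= 0;
  }

  // One blocking flow phase, iterative.
  double blocking_flow(int s, int t) {
    double total = 0.0;
    std::vector<int> path;  // arcs from s to current node
    int u = s;
    for (;;) {
      if (u == t) {
        double bott = R_PosInf;
        for (size_t i = 0; i < path.size(); ++i)
          bott = std::min(bott, cap[path[i]]);
        for (size_t i = 0; i < path.size(); ++i) {
          cap[path[i]] -= bott;
          cap[path[i] ^ 1] += bott;
        }
        // retreat to the tail of the first (shallowest) saturated arc
        size_t keep = path.size();
        for (size_t i = 0; i < path.size(); ++i) {
          if (cap[path[i]] <= EPS) { keep = i; break; }
        }
        path.resize(keep);
        u = path.empty() ? s : to[path.back()];
        total += bott;
        continue;
      }
      int a = it[u];
      bool advanced = false;
      for (; a != -1; a = nxt[a]) {
        if (cap[a] > EPS && level[to[a]] == level[u] + 1) {
          it[u] = a;
          path.push_back(a);
          u = to[a];
          advanced = true;
          break;
        }
      }
      if (!advanced) {
        it[u] = -1;
        level[u] = -1;  // dead end for this phase
        if (u == s) break;
        path.pop_back();
        u = path.empty() ? s : to[path.back()];
      }
    }
    return total;
  }

  double maxflow(int s, int t) {
    double fl = 0.0;
    while (bfs(s, t)) {
      it = head;
      fl += blocking_flow(s, t);
    }
    return fl;
  }
};

}  // namespace

//' @name st_mincut_cpp
//' @title Minimum s-t cut of an undirected capacitated pixel graph
//' @description Internal workhorse: nodes are 1..n_nodes plus an implicit
//'   source and sink. \code{cap_src[i]} is the capacity of the source->i arc
//'   (paid when i falls on the sink side), \code{cap_sink[i]} that of the
//'   i->sink arc. Internal edges are undirected with equal capacity both
//'   ways. Returns the cut value and, for each node, whether it lies on the
//'   source side of the minimum cut.
//' @keywords internal
// [[Rcpp::export]]
List st_mincut_cpp(int n_nodes,
                   IntegerVector edge_from,
                   IntegerVector edge_to,
                   NumericVector edge_cap,
                   NumericVector cap_src,
                   NumericVector cap_sink) {
  if (edge_from.size() != edge_to.size() || edge_from.size() != edge_cap.size())
    stop("edge vectors must have equal length");
  if (cap_src.size() != n_nodes || cap_sink.size() != n_nodes)
    stop("terminal capacity vectors must have length n_nodes");

  const int s = n_nodes, t = n_nodes + 1;
  Dinic g(n_nodes + 2);

  for (int i = 0; i < n_nodes; ++i) {
    if (cap_src[i] > 0) g.add_arc(s, i, cap_src[i], 0.0);
    if (cap_sink[i] > 0) g.add_arc(i, t, cap_sink[i], 0.0);
  }
  for (R_xlen_t e = 0; e < edge_from.size(); ++e) {
    int u = edge_from[e] - 1, v = edge_to[e] - 1;
    if (u < 0 || u >= n_nodes || v < 0 || v >= n_nodes)
      stop("edge endpoint out of range");
    if (edge_cap[e] > 0) g.add_arc(u, v, edge_cap[e], edge_cap[e]);
  }

  double value = g.maxflow(s, t);

  // source side = reachable from s in the residual graph
  LogicalVector src_side(n_nodes, false);
  std::vector<char> seen(n_nodes + 2, 0);
  std::queue<int> q;
  seen[s] = 1; q.push(s);
  while (!q.empty()) {
    int u = q.front(); q.pop();
    for (int a = g.head[u]; a != -1; a = g.nxt[a]) {
      if (g.cap[a] > EPS && !seen[g.to[a]]) {
        seen[g.to[a]] = 1;
        q.push(g.to[a]);
      }
    }
  }
  for (int i = 0; i < n_nodes; ++i) src_side[i] = seen[i] != 0;

  return List::create(_["value"] = value, _["source_side"] = src_side);
}
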