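// Discrete-diffusion substrate detection kernels.
//
// A network is passed as an undirected edge list (0-based, no duplicates,
// no self loops). A "directed pair" indexes a unidirectional conduction
// block: pair p = 2*e + d blocks transmission across edge e from node b to
// node a, where (b, a) = (eu[e], ev[e]) for d = 0 and swapped for d = 1.
// Reentry criterion: the shortest return path b -> ... -> a avoiding edge e,
// plus the blocked edge itself, has length ell; a block induces reentry iff
// ell is finite and ell >= tau.

#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

namespace {

struct Csr {
  int n;
  std::vector<int> head;      // size n+1
  std::vector<int> adj_node;  // size 2m
  std::vector<int> adj_edge;  // size 2m
};

Csr build_csr(int n, const IntegerVector& eu, const IntegerVector& ev) {
  int m = eu.size();
  Csr g;
  g.n = n;
  g.head.assign(n + 1, 0);
  for (int e = 0; e < m; ++e) {
    ++g.head[eu[e] + 1];
    ++g.head[ev[e] + 1];
  }
  for (int i = 0; i < n; ++i) g.head[i + 1] += g.head[i];
  g.adj_node.assign(2 * m, 0);
  g.adj_edge.assign(2 * m, 0);
  std::vector<int> pos(g.head.begin(), g.head.end() - 1);
  for (int e = 0; e < m; ++e) {
    g.adj_node[pos[eu[e]]] = ev[e]; g.adj_edge[pos[eu[e]]++] = e;
    g.adj_node[pos[ev[e]]] = eu[e]; g.adj_edge[pos[ev[e]]++] = e;
  }
  return g;
}

// iterative bridge finding (Tarjan lowlink)
std::vector<bool> find_bridges(const Csr& g, int m) {
  std::vector<bool> bridge(m, false);
  std::vector<int> disc(g.n, -1), low(g.n, 0), it(g.n, 0), par_edge(g.n, -1);
  std::vector<int> stack;
  int timer = 0;
  for (int s = 0; s < g.n; ++s) {
    if (disc[s] != -1) continue;
    stack.push_back(s);
    disc[s] = low[s] = timer++;
    it[s] = g.head[s];
    par_edge[s] = -1;
    while (!stack.empty()) {
      int v = stack.back();
      if (it[v] < g.head[v + 1]) {
        int idx = it[v]++;
        int w = g.adj_node[idx], e = g.adj_edge[idx];
        if (e == par_edge[v]) continue;
        if (disc[w] == -1) {
          disc[w] = low[w] = timer++;
          it[w] = g.head[w];
          par_edge[w] = e;
          stack.push_back(w);
        } else if (disc[w] < low[v]) {
          low[v] = disc[w];
        }
      } else {
        stack.pop_back();
        if (!stack.empty()) {
          int u = stack.back();
          if (low[v] < low[u]) low[u] = low[v];
          if (low[v] > disc[u]) bridge[par_edge[v]] = true;
        }
      }
    }
  }
  return bridge;
}

std::vector<int> bfs_dist(const Csr& g, const IntegerVector& sources) {
  std::vector<int> dist(g.n, -1);
  std::queue<int> q;
  for (int i = 0; i < sources.size(); ++i) {
    int s = sources[i];
    if (dist[s] == -1) { dist[s] = 0; q.push(s); }
  }
  while (!q.empty()) {
    int v = q.front(); q.pop();
    for (int idx = g.head[v]; idx < g.head[v + 1]; ++idx) {
      int w = g.adj_node[idx];
      if (dist[w] == -1) { dist[w] = dist[v] + 1; q.push(w); }
    }
  }
  return dist;
}

} // namespace

// Status per directed pair: 1 reentry, 0 no reentry, -1 not evaluated
// (block site unreachable from the pacing source).
// [[Rcpp::export]]
IntegerVector ddm_oracle_scan_cpp(int n, IntegerVector eu, IntegerVector ev,
                                  int tau, IntegerVector pace) {
  int m = eu.size();
  Csr g = build_csr(n, eu, ev);
  std::vector<bool> bridge = find_bridges(g, m);
  std::vector<int> reach = bfs_dist(g, pace);
  IntegerVector status(2 * m);

  std::vector<int> stamp(n, -1), depth(n, 0);
  std::vector<int> queue_buf(n);
  int scan_id = 0;
  int limit = tau - 2; // a found within this depth => ell <= tau-1 => no reentry

  for (int p = 0; p < 2 * m; ++p) {
    int e = p >> 1, d = p & 1;
    int b = d == 0 ? eu[e] : ev[e];
    int a = d == 0 ? ev[e] : eu[e];
    if (reach[b] < 0) { status[p] = -1; continue; }
    if (bridge[e]) { status[p] = 0; continue; }
    if (limit < 0) { status[p] = 1; continue; } // tau <= 2: any loop suffices
    // truncated BFS from b avoiding edge e, looking for a
    ++scan_id;
    int qh = 0, qt = 0;
    stamp[b] = scan_id; depth[b] = 0;
    queue_buf[qt++] = b;
    bool found = false;
    while (qh < qt && !found) {
      int v = queue_buf[qh++];
      if (depth[v] >= limit) continue;
      for (int idx = g.head[v]; idx < g.head[v + 1]; ++idx) {
        if (g.adj_edge[idx] == e) continue;
        int w = g.adj_node[idx];
        if (stamp[w] == scan_id) continue;
        if (w == a) { found = true; break; }
        stamp[w] = scan_id; depth[w] = depth[v] + 1;
        queue_buf[qt++] = w;
      }
    }
    status[p] = found ? 0 : 1;
  }
  return status;
}

// Shortest return paths for a batch of directed pairs. For pair (b -> a)
// the result is the node sequence b, ..., a of the shortest path avoiding
// edge e (1-based indices); an empty vector means no alternative path.
// [[Rcpp::export]]
List ddm_return_paths_cpp(int n, IntegerVector eu, IntegerVector ev,
                          IntegerVector pairs) {
  Csr g = build_csr(n, eu, ev);
  std::vector<int> stamp(n, -1), par(n, -1), queue_buf(n);
  int scan_id = 0;
  List out(pairs.size());
  for (int k = 0; k < pairs.size(); ++k) {
    int p = pairs[k];
    int e = p >> 1, d = p & 1;
    int b = d == 0 ? eu[e] : ev[e];
    int a = d == 0 ? ev[e] : eu[e];
    ++scan_id;
    int qh = 0, qt = 0;
    stamp[b] = scan_id; par[b] = -1;
    queue_buf[qt++] = b;
    bool found = false;
    while (qh < qt && !found) {
      int v = queue_buf[qh++];
      for (int idx = g.head[v]; idx < g.head[v + 1]; ++idx) {
        if (g.adj_edge[idx] == e) continue;
        int w = g.adj_node[idx];
        if (stamp[w] == scan_id) continue;
        stamp[w] = scan_id; par[w] = v;
        if (w == a) { found = true; break; }
        queue_buf[qt++] = w;
      }
    }
    if (!found) { out[k] = IntegerVector(0); continue; }
    std::vector<int> path;
    for (int v = a; v != -1; v = par[v]) path.push_back(v + 1);
    std::reverse(path.begin(), path.end());
    out[k] = wrap(path);
  }
  return out;
}

// Synchronous excitation / refractory automaton for one unidirectional
// block. Phase 1: a paced wavefront (BFS from `pace`) must reach the block
// site b. Phase 2: quiescent-tissue re-initiation from b with transmission
// b -> a suppressed on its first attempt only. A node excited at time t can
// be re-excited at any time >= t + tau. Reentry = b is excited a second
// time (the wave has re-traversed the blocked site) within max_steps.
// [[Rcpp::export]]
List ddm_simulate_pair_cpp(int n, IntegerVector eu, IntegerVector ev,
                           int pair, int tau, int max_steps,
                           IntegerVector pace) {
  Csr g = build_csr(n, eu, ev);
  int e = pair >> 1, d = pair & 1;
  int b = d == 0 ? eu[e] : ev[e];
  int a = d == 0 ? ev[e] : eu[e];
  std::vector<int> reach = bfs_dist(g, pace);
  if (reach[b] < 0) {
    return List::create(_["reachable"] = false, _["reentry"] = false,
                        _["loop"] = IntegerVector(0),
                        _["arrival"] = NA_INTEGER);
  }
  const int NEVER = INT_MIN / 2;
  std::vector<int> last_exc(n, NEVER), n_exc(n, 0), par(n, -1);
  std::vector<int> frontier, next;
  frontier.push_back(b);
  last_exc[b] = 0; n_exc[b] = 1;
  bool block_used = false, reentry = false;
  int t = 0;
  while (!frontier.empty() && t < max_steps && !reentry) {
    next.clear();
    for (size_t fi = 0; fi < frontier.size(); ++fi) {
      int v = frontier[fi];
      for (int idx = g.head[v]; idx < g.head[v + 1]; ++idx) {
        int w = g.adj_node[idx];
        if (v == b && w == a && g.adj_edge[idx] == e && !block_used) {
          block_used = true; // unidirectional block consumes the first arrival
          continue;
        }
        if (t + 1 - last_exc[w] < tau) continue; // still refractory
        if (last_exc[w] == t + 1) continue;      // already excited this step
        last_exc[w] = t + 1;
        ++n_exc[w];
        if (n_exc[w] == 1) par[w] = v;
        if (w == b && n_exc[b] >= 2) reentry = true;
        next.push_back(w);
      }
    }
    frontier.swap(next);
    ++t;
  }
  IntegerVector loop(0);
  if (reentry && n_exc[a] >= 1) {
    std::vector<int> path;
    for (int v = a; v != -1; v = par[v]) path.push_back(v + 1);
    std::reverse(path.begin(), path.end());
    loop = wrap(path);
  }
  return List::create(_["reachable"] = true, _["reentry"] = reentry,
                      _["loop"] = loop, _["arrival"] = reach[b]);
}

// Reachability (graph distance) from a pacing source; -1 = unreachable.
// [[Rcpp::export]]
IntegerVector ddm_reachability_cpp(int n, IntegerVector eu, IntegerVector ev,
                                   IntegerVector pace) {
  Csr g = build_csr(n, eu, ev);
  return wrap(bfs_dist(g, pace));
}
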