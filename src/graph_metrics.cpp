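// Nodal graph metrics on undirected binary graphs.
//
// All routines take a 0/1 integer adjacency matrix (symmetric, zero
// diagonal; validated on the R side).  Distances are geodesic edge
// counts from breadth-first search; betweenness uses Brandes'
// dependency accumulation.  BFS runs on 64-bit adjacency bitsets so
// that dense brain-parcellation graphs (n of order 10^2, densities up
// to ~0.9) stay cheap; local efficiency reuses the full-graph bitsets
// with the search masked to a node's neighbourhood instead of
// materialising every induced subgraph.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstdint>
using namespace Rcpp;

typedef std::vector< std::vector<int> > AdjList;
typedef std::vector<uint64_t> Bits;

struct BitGraph {
  int n, nw;                 // nodes, 64-bit words per row
  std::vector<uint64_t> row; // n * nw row-major bitsets
  AdjList adj;

  explicit BitGraph(const IntegerMatrix& m)
      : n(m.nrow()), nw((m.nrow() + 63) / 64), row(n * nw, 0), adj(n) {
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        if (m(i, j) != 0) {
          row[(size_t)i * nw + j / 64] |= (uint64_t)1 << (j % 64);
          adj[i].push_back(j);
        }
  }
  bool edge(int i, int j) const {
    return (row[(size_t)i * nw + j / 64] >> (j % 64)) & 1;
  }
};

// level-synchronous BFS over bitsets; only nodes with mask bit set are
// traversable.  dist is -1 for nodes never reached (or outside mask).
static void bfs_bits(const BitGraph& g, int src, const Bits& mask,
                     std::vector<int>& dist) {
  std::fill(dist.begin(), dist.end(), -1);
  Bits visited(g.nw, 0), frontier(g.nw, 0), next(g.nw, 0);
  frontier[src / 64] |= (uint64_t)1 << (src % 64);
  visited = frontier;
  dist[src] = 0;
  int level = 0;
  bool any = true;
  while (any) {
    ++level;
    std::fill(next.begin(), next.end(), 0);
    for (int w = 0; w < g.nw; ++w) {
      uint64_t bits = frontier[w];
      while (bits) {
        int v = w * 64 + __builtin_ctzll(bits);
        bits &= bits - 1;
        const uint64_t* rv = &g.row[(size_t)v * g.nw];
        for (int u = 0; u < g.nw; ++u) next[u] |= rv[u];
      }
    }
    any = false;
    for (int w = 0; w < g.nw; ++w) {
      next[w] &= mask[w] & ~visited[w];
      visited[w] |= next[w];
      uint64_t bits = next[w];
      while (bits) {
        int v = w * 64 + __builtin_ctzll(bits);
        bits &= bits - 1;
        dist[v] = level;
        any = true;
      }
    }
    frontier = next;
  }
}

static Bits full_mask(int n, int nw) {
  Bits mask(nw, 0);
  for (int i = 0; i < n; ++i) mask[i / 64] |= (uint64_t)1 << (i % 64);
  return mask;
}

// [[Rcpp::export]]
IntegerMatrix graph_distances_cpp(IntegerMatrix adj) {
  BitGraph g(adj);
  IntegerMatrix d(g.n, g.n);
  Bits mask = full_mask(g.n, g.nw);
  std::vector<int> dist(g.n);
  for (int s = 0; s < g.n; ++s) {
    bfs_bits(g, s, mask, dist);
    for (int j = 0; j < g.n; ++j) d(s, j) = dist[j];
  }
  return d;
}

// Brandes (2001) betweenness; returns raw unordered-pair counts
// (each s,t pair counted once).
static std::vector<double> brandes(const BitGraph& g) {
  const int n = g.n;
  std::vector<double> bc(n, 0.0), sigma(n), delta(n);
  std::vector<int> dist(n);
  std::vector< std::vector<int> > pred(n);
  std::vector<int> order;
  order.reserve(n);

  for (int s = 0; s < n; ++s) {
    order.clear();
    for (int i = 0; i < n; ++i) { pred[i].clear(); sigma[i] = 0.0; dist[i] = -1; }
    sigma[s] = 1.0; dist[s] = 0;
    std::queue<int> q;
    q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      order.push_back(v);
      for (size_t k = 0; k < g.adj[v].size(); ++k) {
        int w = g.adj[v][k];
        if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
        if (dist[w] == dist[v] + 1) { sigma[w] += sigma[v]; pred[w].push_back(v); }
      }
    }
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int k = (int)order.size() - 1; k >= 0; --k) {
      int w = order[k];
      for (size_t p = 0; p < pred[w].size(); ++p) {
        int v = pred[w][p];
        delta[v] += (sigma[v] / sigma[w]) * (1.0 + delta[w]);
      }
      if (w != s) bc[w] += delta[w];
    }
  }
  // each unordered pair was visited from both endpoints
  for (int i = 0; i < n; ++i) bc[i] /= 2.0;
  return bc;
}

// [[Rcpp::export]]
NumericVector betweenness_raw_cpp(IntegerMatrix adj) {
  BitGraph g(adj);
  return wrap(brandes(g));
}

// Seven nodal metrics in one pass.  Columns: degree, cost,
// global_efficiency, local_efficiency, betweenness, path_length,
// clustering.  Conventions for degenerate nodes: isolated nodes get
// path_length 0; nodes with degree < 2 get clustering 0 and local
// efficiency 0; unreachable pairs contribute 0 to global efficiency
// and are dropped from path_length.
// [[Rcpp::export]]
NumericMatrix nodal_metrics_cpp(IntegerMatrix adj) {
  BitGraph g(adj);
  const int n = g.n;
  NumericMatrix out(n, 7);
  Bits mask = full_mask(n, g.nw);
  std::vector<int> dist(n);

  for (int i = 0; i < n; ++i) {
    const std::vector<int>& nb = g.adj[i];
    const int deg = (int)nb.size();
    out(i, 0) = deg;
    out(i, 1) = n > 1 ? (double)deg / (n - 1) : 0.0;

    bfs_bits(g, i, mask, dist);
    double inv_sum = 0.0, d_sum = 0.0;
    int n_reach = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i || dist[j] < 0) continue;
      inv_sum += 1.0 / dist[j];
      d_sum += dist[j];
      ++n_reach;
    }
    out(i, 2) = n > 1 ? inv_sum / (n - 1) : 0.0;
    out(i, 5) = n_reach > 0 ? d_sum / n_reach : 0.0;

    // clustering: edges among neighbours
    if (deg >= 2) {
      int e = 0;
      for (int p = 0; p < deg; ++p)
        for (int q = p + 1; q < deg; ++q)
          if (g.edge(nb[p], nb[q])) ++e;
      out(i, 6) = 2.0 * e / ((double)deg * (deg - 1));
    } else {
      out(i, 6) = 0.0;
    }

    // local efficiency: mean inverse distance inside the subgraph
    // induced by the neighbours of i (BFS masked to the neighbourhood)
    if (deg >= 2) {
      Bits nmask(g.nw, 0);
      for (int p = 0; p < deg; ++p)
        nmask[nb[p] / 64] |= (uint64_t)1 << (nb[p] % 64);
      double s_inv = 0.0;
      for (int p = 0; p < deg; ++p) {
        bfs_bits(g, nb[p], nmask, dist);
        for (int q = 0; q < deg; ++q) {
          int d = dist[nb[q]];
          if (nb[q] != nb[p] && d > 0) s_inv += 1.0 / d;
        }
      }
      out(i, 3) = s_inv / ((double)deg * (deg - 1));
    } else {
      out(i, 3) = 0.0;
    }
  }

  // normalized betweenness
  std::vector<double> bc = brandes(g);
  const double norm = n > 2 ? (double)(n - 1) * (n - 2) / 2.0 : 1.0;
  for (int i = 0; i < n; ++i) out(i, 4) = bc[i] / norm;

  return out;
}
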