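#include <Rcpp.h>
using namespace Rcpp;

// Degree-preserving randomization of small binary networks by
// Maslov-Sneppen double-edge swaps, plus the two null statistics
// (mean nodal clustering, characteristic path length) needed to
// normalize small-worldness over ensembles of hundreds of nulls per
// (subject, threshold) cell. All randomness comes from R's RNG so a
// set.seed() call in R makes ensembles reproducible.

namespace {

struct Graph {
  int n;
  std::vector<unsigned char> adj;  // flat n x n, small n
  std::vector<std::pair<int, int> > edges;

  Graph(int n_, const IntegerMatrix& e) : n(n_), adj(n_ * n_, 0) {
    for (int k = 0; k < e.nrow(); ++k) {
      int a = e(k, 0) - 1, b = e(k, 1) - 1;
      at(a, b) = at(b, a) = 1;
      edges.push_back(std::make_pair(a, b));
    }
  }
  inline unsigned char& at(int i, int j) { return adj[i * n + j]; }
  inline unsigned char at(int i, int j) const { return adj[i * n + j]; }
};

// attempts swaps in place; invalid proposals (self-loop, duplicate edge,
// shared endpoint) are rejected, preserving the exact degree sequence
void double_edge_swap(Graph& g, int n_attempts) {
  int E = (int)g.edges.size();
  if (E < 2) return;
  for (int it = 0; it < n_attempts; ++it) {
    int e1 = (int)(unif_rand() * E);
    int e2 = (int)(unif_rand() * E);
    if (e1 >= E) e1 = E - 1;
    if (e2 >= E) e2 = E - 1;
    if (e1 == e2) continue;
    int a = g.edges[e1].first, b = g.edges[e1].second;
    int c = g.edges[e2].first, d = g.edges[e2].second;
    if (unif_rand() < 0.5) std::swap(c, d);
    // propose (a,d) and (c,b)
    if (a == d || c == b) continue;
    if (a == c || b == d) continue;
    if (g.at(a, d) || g.at(c, b)) continue;
    g.at(a, b) = g.at(b, a) = 0;
    g.at(c, d) = g.at(d, c) = 0;
    g.at(a, d) = g.at(d, a) = 1;
    g.at(c, b) = g.at(b, c) = 1;
    g.edges[e1] = std::make_pair(a, d);
    g.edges[e2] = std::make_pair(c, b);
  }
}

// mean over nodes of the local clustering coefficient (0 when degree < 2)
double mean_clustering(const Graph& g) {
  double total = 0.0;
  for (int v = 0; v < g.n; ++v) {
    std::vector<int> nb;
    for (int u = 0; u < g.n; ++u)
      if (g.at(v, u)) nb.push_back(u);
    int k = (int)nb.size();
    if (k < 2) continue;
    int tri = 0;
    for (int i = 0; i < k; ++i)
      for (int j = i + 1; j < k; ++j)
        if (g.at(nb[i], nb[j])) ++tri;
    total += 2.0 * tri / (k * (k - 1.0));
  }
  return total / g.n;
}

// mean geodesic distance over ordered pairs with a finite distance
double char_path_length(const Graph& g) {
  double total = 0.0;
  long count = 0;
  std::vector<int> dist(g.n), queue(g.n);
  for (int s = 0; s < g.n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    int head = 0, tail = 0;
    queue[tail++] = s;
    while (head < tail) {
      int v = queue[head++];
      for (int u = 0; u < g.n; ++u) {
        if (g.at(v, u) && dist[u] < 0) {
          dist[u] = dist[v] + 1;
          queue[tail++] = u;
        }
      }
    }
    for (int u = 0; u < g.n; ++u) {
      if (u != s && dist[u] > 0) {
        total += dist[u];
        ++count;
      }
    }
  }
  if (count == 0) return NA_REAL;
  return total / count;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_null_stats")]]
NumericMatrix cpp_null_stats(IntegerMatrix edges, int nNodes, int nNull,
                             int swapsPerEdge) {
  NumericMatrix out(nNull, 2);
  int attempts = swapsPerEdge * edges.nrow();
  for (int r = 0; r < nNull; ++r) {
    Graph g(nNodes, edges);
    double_edge_swap(g, attempts);
    out(r, 0) = mean_clustering(g);
    out(r, 1) = char_path_length(g);
  }
  colnames(out) = CharacterVector::create("clustering", "path_length");
  return out;
}

// [[Rcpp::export(name = ".cpp_null_ensemble")]]
List cpp_null_ensemble(IntegerMatrix edges, int nNodes, int nNull,
                       int swapsPerEdge) {
  List out(nNull);
  int attempts = swapsPerEdge * edges.nrow();
  for (int r = 0; r < nNull; ++r) {
    Graph g(nNodes, edges);
    double_edge_swap(g, attempts);
    IntegerMatrix e((int)g.edges.size(), 2);
    for (int k = 0; k < (int)g.edges.size(); ++k) {
      e(k, 0) = g.edges[k].first + 1;
      e(k, 1) = g.edges[k].second + 1;
    }
    out[r] = e;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_graph_stats")]]
NumericVector cpp_graph_stats(IntegerMatrix edges, int nNodes) {
  Graph g(nNodes, edges);
  NumericVector out = NumericVector::create(
      _["clustering"] = mean_clustering(g),
      _["path_length"] = char_path_length(g));
  return out;
}
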