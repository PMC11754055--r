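#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <queue>
#include <stack>
using namespace Rcpp;

// Unweighted graph metric kernels for the sparsity sweep. All operate on a
// dense 0/1 symmetric adjacency with zero diagonal; distances are BFS hop
// counts, betweenness is Brandes' algorithm, and nodal local efficiency is
// the global efficiency of each node's neighbour-induced subgraph.

static std::vector<std::vector<int>> adj_list(const IntegerMatrix& A) {
  int n = A.nrow();
  std::vector<std::vector<int>> adj(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (A(i, j) != 0) adj[i].push_back(j);
  return adj;
}

// BFS distances from every source; unreachable pairs get -1
static std::vector<std::vector<int>> bfs_all(
    const std::vector<std::vector<int>>& adj) {
  int n = adj.size();
  std::vector<std::vector<int>> D(n, std::vector<int>(n, -1));
  std::vector<int> q(n);
  for (int s = 0; s < n; ++s) {
    int head = 0, tail = 0;
    D[s][s] = 0;
    q[tail++] = s;
    while (head < tail) {
      int v = q[head++];
      for (int w : adj[v]) {
        if (D[s][w] < 0) {
          D[s][w] = D[s][v] + 1;
          q[tail++] = w;
        }
      }
    }
  }
  return D;
}

// [[Rcpp::export(name = ".cpp_distances")]]
NumericMatrix cpp_distances(IntegerMatrix A) {
  auto adj = adj_list(A);
  auto D = bfs_all(adj);
  int n = A.nrow();
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      out(i, j) = D[i][j] < 0 ? R_PosInf : D[i][j];
  return out;
}

// bitset rows of the adjacency matrix: word w of row i holds neighbours
// 64*w .. 64*w+63, enabling set intersections via popcount
static std::vector<uint64_t> bit_rows(const IntegerMatrix& A, int& words) {
  int n = A.nrow();
  words = (n + 63) / 64;
  std::vector<uint64_t> bits((size_t)n * words, 0ULL);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (A(i, j) != 0) bits[(size_t)i * words + j / 64] |= 1ULL << (j % 64);
  return bits;
}

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

// local clustering coefficient per node (triangles over possible
// neighbour pairs); degree < 2 contributes 0
// [[Rcpp::export(name = ".cpp_local_clustering")]]
NumericVector cpp_local_clustering(IntegerMatrix A) {
  int n = A.nrow(), words = 0;
  auto bits = bit_rows(A, words);
  auto adj = adj_list(A);
  NumericVector cc(n);
  for (int i = 0; i < n; ++i) {
    int k = adj[i].size();
    if (k < 2) { cc[i] = 0.0; continue; }
    long links2 = 0;  // twice the number of edges among neighbours
    const uint64_t* ni = &bits[(size_t)i * words];
    for (int a : adj[i]) {
      const uint64_t* na = &bits[(size_t)a * words];
      for (int w = 0; w < words; ++w) links2 += popcount64(ni[w] & na[w]);
    }
    cc[i] = (double)links2 / (k * (k - 1.0));
  }
  return cc;
}

// global efficiency of the subgraph induced by `nodes` (given as mask +
// list), via frontier-expansion BFS on the bitset rows
static double subgraph_efficiency(const std::vector<uint64_t>& bits,
                                  int words,
                                  const std::vector<uint64_t>& mask,
                                  const std::vector<int>& nodes) {
  int k = nodes.size();
  if (k < 2) return 0.0;
  std::vector<uint64_t> visited(words), frontier(words), next(words);
  double total = 0.0;
  for (int a : nodes) {
    std::fill(visited.begin(), visited.end(), 0ULL);
    std::fill(frontier.begin(), frontier.end(), 0ULL);
    visited[a / 64] |= 1ULL << (a % 64);
    frontier[a / 64] |= 1ULL << (a % 64);
    int d = 0;
    while (true) {
      std::fill(next.begin(), next.end(), 0ULL);
      bool empty = true;
      for (int w = 0; w < words; ++w) {
        uint64_t f = frontier[w];
        while (f) {
          int v = 64 * w + __builtin_ctzll(f);
          f &= f - 1;
          const uint64_t* nv = &bits[(size_t)v * words];
          for (int u = 0; u < words; ++u) next[u] |= nv[u];
        }
      }
      ++d;
      int reached = 0;
      for (int w = 0; w < words; ++w) {
        next[w] &= mask[w] & ~visited[w];
        visited[w] |= next[w];
        reached += popcount64(next[w]);
        if (next[w]) empty = false;
      }
      if (empty) break;
      total += (double)reached / d;
      std::swap(frontier, next);
    }
  }
  return total / (k * (k - 1.0));
}

// [[Rcpp::export(name = ".cpp_nodal_local_efficiency")]]
NumericVector cpp_nodal_local_efficiency(IntegerMatrix A) {
  int n = A.nrow(), words = 0;
  auto bits = bit_rows(A, words);
  auto adj = adj_list(A);
  NumericVector nle(n);
  std::vector<uint64_t> mask(words);
  for (int i = 0; i < n; ++i) {
    for (int w = 0; w < words; ++w) mask[w] = bits[(size_t)i * words + w];
    nle[i] = subgraph_efficiency(bits, words, mask, adj[i]);
  }
  return nle;
}

// Brandes' betweenness centrality, undirected, unnormalised
// [[Rcpp::export(name = ".cpp_betweenness")]]
NumericVector cpp_betweenness(IntegerMatrix A) {
  int n = A.nrow();
  auto adj = adj_list(A);
  NumericVector bc(n);
  std::vector<double> sigma(n), delta(n);
  std::vector<int> dist(n), q(n);
  std::vector<std::vector<int>> pred(n);
  for (int s = 0; s < n; ++s) {
    std::stack<int> order;
    for (int i = 0; i < n; ++i) {
      pred[i].clear();
      sigma[i] = 0.0;
      delta[i] = 0.0;
      dist[i] = -1;
    }
    sigma[s] = 1.0;
    dist[s] = 0;
    int head = 0, tail = 0;
    q[tail++] = s;
    while (head < tail) {
      int v = q[head++];
      order.push(v);
      for (int w : adj[v]) {
        if (dist[w] < 0) {
          dist[w] = dist[v] + 1;
          q[tail++] = w;
        }
        if (dist[w] == dist[v] + 1) {
          sigma[w] += sigma[v];
          pred[w].push_back(v);
        }
      }
    }
    while (!order.empty()) {
      int w = order.top();
      order.pop();
      for (int v : pred[w])
        delta[v] += sigma[v] / sigma[w] * (1.0 + delta[w]);
      if (w != s) bc[w] += delta[w];
    }
  }
  // each unordered pair was counted from both end points
  for (int i = 0; i < n; ++i) bc[i] /= 2.0;
  return bc;
}

// Full sparsity sweep in one call: edges come ranked by descending weight
// (1-based node indices), k_per_threshold gives the retained edge count at
// each threshold (non-decreasing: edge sets are nested). Returns the global
// curves (cp, lp, eg, eloc), the nodal curves (ne, dc, nle, bc) and a
// per-threshold disconnection flag.
// [[Rcpp::export(name = ".cpp_sweep")]]
List cpp_sweep(IntegerMatrix edges, int n, IntegerVector k_per_threshold) {
  int nt = k_per_threshold.size();
  NumericMatrix glob(nt, 4);
  colnames(glob) = CharacterVector::create("cp", "lp", "eg", "eloc");
  NumericMatrix ne(n, nt), dc(n, nt), nle(n, nt), bc(n, nt);
  LogicalVector disconnected(nt);

  for (int t = 0; t < nt; ++t) {
    int k = k_per_threshold[t];
    IntegerMatrix A(n, n);
    for (int e = 0; e < k; ++e) {
      int i = edges(e, 0) - 1, j = edges(e, 1) - 1;
      A(i, j) = 1;
      A(j, i) = 1;
    }
    auto adj = adj_list(A);

    NumericVector cc = cpp_local_clustering(A);
    glob(t, 0) = mean(cc);

    auto D = bfs_all(adj);
    double lp_sum = 0.0, eg_sum = 0.0;
    long lp_pairs = 0;
    bool disc = false;
    for (int i = 0; i < n; ++i) {
      double ne_i = 0.0;
      for (int j = 0; j < n; ++j) {
        if (i == j) continue;
        if (D[i][j] < 0) { disc = true; continue; }
        ne_i += 1.0 / D[i][j];
        if (j > i) { lp_sum += D[i][j]; ++lp_pairs; }
      }
      ne(i, t) = ne_i / (n - 1.0);
      eg_sum += ne_i;
      dc(i, t) = adj[i].size();
    }
    glob(t, 1) = lp_pairs > 0 ? lp_sum / lp_pairs : NA_REAL;
    glob(t, 2) = eg_sum / (n * (n - 1.0));
    disconnected[t] = disc;

    NumericVector nl = cpp_nodal_local_efficiency(A);
    nle(_, t) = nl;
    glob(t, 3) = mean(nl);

    bc(_, t) = cpp_betweenness(A);
  }
  return List::create(_["global"] = glob, _["ne"] = ne, _["dc"] = dc,
                      _["nle"] = nle, _["bc"] = bc,
                      _["disconnected"] = disconnected);
}
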