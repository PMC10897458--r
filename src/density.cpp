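#include <Rcpp.h>
#include <unordered_map>
#include <functional>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Fixed-radius neighborhoods via grid hashing (cell = eps), d = 2 or 3.
// Neighbor counts include the point itself, matching the usual min_samples
// convention of density-based clustering.

namespace {

struct Grid {
  double eps;
  int d;
  const NumericMatrix& pts;
  std::unordered_map<int64_t, std::vector<int> > cells;

  Grid(const NumericMatrix& p, double e) : eps(e), d(p.ncol()), pts(p) {
    for (int i = 0; i < p.nrow(); ++i) cells[key(i)].push_back(i);
  }
  int64_t hash(int64_t cx, int64_t cy, int64_t cz) const {
    // coordinates are bounded (standardized/minmax data); offset avoids negatives
    const int64_t B = 1 << 20, O = 1 << 19;
    return ((cx + O) * B + (cy + O)) * B + (cz + O);
  }
  int64_t key(int i) const {
    int64_t cx = (int64_t)std::floor(pts(i, 0) / eps);
    int64_t cy = (int64_t)std::floor(pts(i, 1) / eps);
    int64_t cz = d > 2 ? (int64_t)std::floor(pts(i, 2) / eps) : 0;
    return hash(cx, cy, cz);
  }
  void neighbors(int i, std::vector<int>& out) const {
    out.clear();
    int64_t cx = (int64_t)std::floor(pts(i, 0) / eps);
    int64_t cy = (int64_t)std::floor(pts(i, 1) / eps);
    int64_t cz = d > 2 ? (int64_t)std::floor(pts(i, 2) / eps) : 0;
    double e2 = eps * eps;
    int zlo = d > 2 ? -1 : 0, zhi = d > 2 ? 1 : 0;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = zlo; dz <= zhi; ++dz) {
          auto it = cells.find(hash(cx + dx, cy + dy, cz + dz));
          if (it == cells.end()) continue;
          for (int j : it->second) {
            double s = 0;
            for (int k = 0; k < d; ++k) {
              double t = pts(i, k) - pts(j, k);
              s += t * t;
            }
            if (s <= e2) out.push_back(j);
          }
        }
  }
};

} // namespace

// [[Rcpp::export]]
IntegerVector cpp_dbscan(NumericMatrix pts, double eps, int min_pts) {
  int n = pts.nrow();
  IntegerVector labels(n, -1);           // -1 = noise
  if (n == 0) return labels;
  Grid grid(pts, eps);
  std::vector<int> nb, nb2;
  std::vector<char> visited(n, 0);
  int cl = 0;
  for (int i = 0; i < n; ++i) {
    if (visited[i]) continue;
    visited[i] = 1;
    grid.neighbors(i, nb);
    if ((int)nb.size() < min_pts) continue; // stays noise unless claimed later
    ++cl;
    labels[i] = cl;
    std::queue<int> q;
    for (int j : nb) if (j != i) q.push(j);
    while (!q.empty()) {
      int j = q.front(); q.pop();
      if (labels[j] == -1) labels[j] = cl;  // border point
      if (visited[j]) continue;
      visited[j] = 1;
      labels[j] = cl;
      grid.neighbors(j, nb2);
      if ((int)nb2.size() >= min_pts)
        for (int k : nb2) if (!visited[k] || labels[k] == -1) q.push(k);
    }
  }
  return labels;
}

// Prim minimum spanning tree under the mutual-reachability metric
// d_mr(a, b) = max(core[a], core[b], d(a, b)).  O(n^2) time, O(n) memory;
// all comparisons run on squared distances, the square root is taken once
// per accepted edge.
// [[Rcpp::export]]
NumericMatrix cpp_mst_mutual_reach(NumericMatrix pts, NumericVector core) {
  int n = pts.nrow(), d = pts.ncol();
  if (n < 2) return NumericMatrix(0, 3);
  std::vector<double> P((size_t)n * d);   // row-major copy for cache locality
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < d; ++k) P[(size_t)i * d + k] = pts(i, k);
  std::vector<double> core2(n);
  for (int i = 0; i < n; ++i) core2[i] = core[i] * core[i];
  std::vector<double> best(n, R_PosInf);
  std::vector<int> from(n, 0);
  std::vector<char> in_tree(n, 0);
  NumericMatrix edges(n - 1, 3);
  int cur = 0;
  in_tree[0] = 1;
  for (int e = 0; e < n - 1; ++e) {
    const double* pc = &P[(size_t)cur * d];
    const double cc = core2[cur];
    int nxt = -1;
    double nb = R_PosInf;
    for (int j = 0; j < n; ++j) {
      if (in_tree[j]) continue;
      const double* pj = &P[(size_t)j * d];
      double s = 0;
      for (int k = 0; k < d; ++k) {
        double t = pc[k] - pj[k];
        s += t * t;
      }
      if (cc > s) s = cc;
      if (core2[j] > s) s = core2[j];
      if (s < best[j]) { best[j] = s; from[j] = cur; }
      if (best[j] < nb) { nb = best[j]; nxt = j; }
    }
    edges(e, 0) = from[nxt] + 1;
    edges(e, 1) = nxt + 1;
    edges(e, 2) = std::sqrt(best[nxt]);
    in_tree[nxt] = 1;
    cur = nxt;
  }
  return edges;
}

// Single-linkage merge tree from MST edges sorted by ascending weight.
// Leaves are 1..n; internal nodes n+1..2n-1 in merge order.  Returns a
// (n-1) x 4 matrix: left child, right child, merge distance, subtree size.
// [[Rcpp::export]]
NumericMatrix cpp_single_linkage(IntegerVector from, IntegerVector to,
                                 NumericVector w, int n) {
  int m = from.size();
  std::vector<int> parent(2 * n, 0), node_of(2 * n, 0);
  std::vector<double> size(2 * n, 1.0);
  for (int i = 1; i <= n; ++i) { parent[i] = i; node_of[i] = i; }
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  NumericMatrix out(m, 4);
  int next_node = n;
  for (int e = 0; e < m; ++e) {
    int a = find(from[e]), b = find(to[e]);
    ++next_node;
    out(e, 0) = node_of[a];
    out(e, 1) = node_of[b];
    out(e, 2) = w[e];
    out(e, 3) = size[a] + size[b];
    parent[b] = a;
    node_of[a] = next_node;
    size[a] += size[b];
  }
  return out;
}
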