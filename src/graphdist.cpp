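#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Sum and count of finite shortest-path distances (in edges) over all ordered
// pairs of distinct vertices, by breadth-first search from every vertex.
// adj/ptr: CSR adjacency (0-based); ptr has length n+1.
// [[Rcpp::export]]
NumericVector bfs_pair_stats_cpp(int n, IntegerVector adj, IntegerVector ptr) {
  std::vector<int> dist(n);
  double total = 0.0, npairs = 0.0;
  std::queue<int> q;
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int e = ptr[u]; e < ptr[u + 1]; ++e) {
        int v = adj[e];
        if (dist[v] < 0) { dist[v] = dist[u] + 1; q.push(v); }
      }
    }
    for (int v = 0; v < n; ++v) {
      if (v != s && dist[v] > 0) { total += dist[v]; npairs += 1.0; }
    }
  }
  return NumericVector::create(total, npairs);
}

// Local thickness by disc painting (Hildebrand-style 2D approximation).
// dist: Euclidean distance map of the foreground (0 on background).
// Every foreground pixel p gets the diameter 2*(d_c - 0.5) of the largest
// disc, centred at any foreground pixel c with radius d_c - 0.5, that covers
// p.  Centres are processed in decreasing radius order; a centre already
// covered by a disc at least as large as its own contributes nothing and is
// skipped, which prunes the quadratic cost to roughly the medial set.
// [[Rcpp::export]]
NumericMatrix local_thickness_cpp(NumericMatrix dist) {
  int nr = dist.nrow(), nc = dist.ncol();
  NumericMatrix th(nr, nc);
  std::vector<std::pair<double, int> > centers;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (dist(r, c) > 0) centers.push_back(std::make_pair(dist(r, c), r + c * nr));
  std::sort(centers.begin(), centers.end(),
            [](const std::pair<double, int> &a, const std::pair<double, int> &b) {
              if (a.first != b.first) return a.first > b.first;
              return a.second < b.second;
            });
  for (size_t i = 0; i < centers.size(); ++i) {
    double d = centers[i].first;
    int idx = centers[i].second;
    int r0 = idx % nr, c0 = idx / nr;
    double rad = d - 0.5;
    if (rad <= 0) rad = 0.0;
    double diam = 2.0 * rad;
    if (th(r0, c0) >= diam && diam > 0) continue;  // inside a larger disc
    int ri = (int)std::floor(rad);
    double rad2 = rad * rad;
    for (int dr = -ri; dr <= ri; ++dr) {
      int r = r0 + dr;
      if (r < 0 || r >= nr) continue;
      for (int dc = -ri; dc <= ri; ++dc) {
        int c = c0 + dc;
        if (c < 0 || c >= nc) continue;
        if (dr * dr + dc * dc > rad2) continue;
        if (dist(r, c) <= 0) continue;
        if (th(r, c) < diam) th(r, c) = diam;
      }
    }
    if (th(r0, c0) < diam) th(r0, c0) = diam;
    // radius 0 centres (diam 0): still mark with a one-pixel thickness
    if (th(r0, c0) <= 0) th(r0, c0) = 1.0;
  }
  // any foreground pixel never painted (thin single-pixel structures)
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (dist(r, c) > 0 && th(r, c) <= 0) th(r, c) = 1.0;
  return th;
}
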