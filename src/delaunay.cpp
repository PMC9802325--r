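#include <Rcpp.h>
using namespace Rcpp;

// Brute-force Delaunay triangulation of points in general position.
// Checks every triple (i,j,k): it is a Delaunay triangle iff no other point
// lies strictly inside its circumcircle.  O(n^4) worst case but adequate for
// the phantom's seed counts (a few hundred points); errors out above n = 1200.
// Returns 1-based triangle vertex indices and circumcentres (x, y).
// [[Rcpp::export]]
List delaunay_cpp(NumericVector x, NumericVector y) {
  int n = x.size();
  if (n < 3) stop("need at least 3 points");
  if (n > 1200) stop("too many points for brute-force triangulation");
  std::vector<int> ti, tj, tk;
  std::vector<double> cx, cy;
  // scale for degeneracy tolerance
  double xmin = min(x), xmax = max(x), ymin = min(y), ymax = max(y);
  double scale = std::max(xmax - xmin, ymax - ymin);
  if (scale <= 0) scale = 1.0;
  double areaEps = 1e-10 * scale * scale;
  for (int i = 0; i < n - 2; ++i) {
    for (int j = i + 1; j < n - 1; ++j) {
      double dxij = x[j] - x[i], dyij = y[j] - y[i];
      for (int k = j + 1; k < n; ++k) {
        double dxik = x[k] - x[i], dyik = y[k] - y[i];
        double cross = dxij * dyik - dyij * dxik;
        if (std::fabs(cross) < areaEps) continue;  // (near-)collinear
        // circumcentre
        double b = dxij * dxij + dyij * dyij;
        double c = dxik * dxik + dyik * dyik;
        double ux = x[i] + (dyik * b - dyij * c) / (2.0 * cross);
        double uy = y[i] + (dxij * c - dxik * b) / (2.0 * cross);
        double r2 = (x[i] - ux) * (x[i] - ux) + (y[i] - uy) * (y[i] - uy);
        double lim = r2 * (1.0 - 1e-12);
        bool ok = true;
        for (int m = 0; m < n; ++m) {
          if (m == i || m == j || m == k) continue;
          double d2 = (x[m] - ux) * (x[m] - ux) + (y[m] - uy) * (y[m] - uy);
          if (d2 < lim) { ok = false; break; }
        }
        if (ok) {
          ti.push_back(i + 1); tj.push_back(j + 1); tk.push_back(k + 1);
          cx.push_back(ux); cy.push_back(uy);
        }
      }
    }
  }
  int nt = (int)ti.size();
  IntegerMatrix tri(nt, 3);
  NumericMatrix cc(nt, 2);
  for (int t = 0; t < nt; ++t) {
    tri(t, 0) = ti[t]; tri(t, 1) = tj[t]; tri(t, 2) = tk[t];
    cc(t, 0) = cx[t]; cc(t, 1) = cy[t];
  }
  return List::create(_["triangles"] = tri, _["circumcenters"] = cc);
}
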