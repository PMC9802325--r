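#include <Rcpp.h>
using namespace Rcpp;

// 8-neighbour offsets, index 0..7 = E, NE, N, NW, W, SW, S, SE
static const int DR[8] = { 0, -1, -1, -1,  0,  1,  1,  1 };
static const int DC[8] = { 1,  1,  0, -1, -1, -1,  0,  1 };

static inline bool fg(const LogicalMatrix &m, int r, int c) {
  if (r < 0 || c < 0 || r >= m.nrow() || c >= m.ncol()) return false;
  return m(r, c) == TRUE;
}

static inline int nbcount(const LogicalMatrix &m, int r, int c) {
  int n = 0;
  for (int k = 0; k < 8; ++k) if (fg(m, r + DR[k], c + DC[k])) ++n;
  return n;
}

// Yokoi connectivity number for 8-connected foreground.
// p is a simple point (deletable without changing topology) iff C == 1.
static inline int yokoi8(const LogicalMatrix &m, int r, int c) {
  int x[8];
  for (int k = 0; k < 8; ++k) x[k] = fg(m, r + DR[k], c + DC[k]) ? 1 : 0;
  int C = 0;
  for (int k = 0; k < 8; k += 2) {
    int xb  = 1 - x[k];
    int xb1 = 1 - x[(k + 1) % 8];
    int xb2 = 1 - x[(k + 2) % 8];
    C += xb - xb * xb1 * xb2;
  }
  return C;
}

// Topology-preserving medial-line thinning.
// Sequential deletion of simple points (Yokoi connectivity number == 1) that
// are not endpoints, in four directional subiterations (require background on
// the N/S/E/W side respectively) until stable.  Sequential re-checking makes
// every deletion individually topology-safe, so 8-connected component
// structure of the mask is preserved exactly.  A final pass thins residual
// 2x2 blocks where a member pixel is still deletable; blocks that cannot be
// thinned without changing topology (possible at dense junctions) are kept.
// [[Rcpp::export]]
LogicalMatrix thin_cpp(LogicalMatrix mask) {
  LogicalMatrix m = clone(mask);
  int nr = m.nrow(), nc = m.ncol();
  // directional background requirement: N, S, E, W neighbour indices
  static const int DIRS[4] = { 2, 6, 0, 4 };
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 4; ++d) {
      int dr = DR[DIRS[d]], dc = DC[DIRS[d]];
      // two-phase: collect the directional border as of the pass start, so
      // deletions cannot expose new candidates within the same pass (that
      // would erode whole arms in scan order); then delete sequentially,
      // re-checking simplicity so every deletion stays topology-safe.
      std::vector<int> cand;
      for (int r = 0; r < nr; ++r)
        for (int c = 0; c < nc; ++c)
          if (m(r, c) == TRUE && !fg(m, r + dr, c + dc))
            cand.push_back(r * nc + c);
      for (size_t i = 0; i < cand.size(); ++i) {
        int r = cand[i] / nc, c = cand[i] % nc;
        if (m(r, c) != TRUE) continue;
        int nb = nbcount(m, r, c);
        if (nb <= 1) continue;                 // keep endpoints / isolated
        if (yokoi8(m, r, c) != 1) continue;    // not simple
        m(r, c) = FALSE;
        changed = true;
      }
    }
    // 2x2 cleanup runs only once the directional passes are stable; its
    // deletions loop back into another directional cycle, so the returned
    // skeleton is a fixed point of the whole procedure.
    if (changed) continue;
    // 2x2 block cleanup (still topology-safe and endpoint-preserving)
    for (int r = 0; r + 1 < nr; ++r) {
      for (int c = 0; c + 1 < nc; ++c) {
        if (m(r, c) == TRUE && m(r + 1, c) == TRUE &&
            m(r, c + 1) == TRUE && m(r + 1, c + 1) == TRUE) {
          const int rr[4] = { r, r, r + 1, r + 1 };
          const int cc[4] = { c, c + 1, c, c + 1 };
          for (int k = 0; k < 4; ++k) {
            if (m(rr[k], cc[k]) == TRUE && nbcount(m, rr[k], cc[k]) > 1 &&
                yokoi8(m, rr[k], cc[k]) == 1) {
              m(rr[k], cc[k]) = FALSE;
              changed = true;
              break;
            }
          }
        }
      }
    }
  }
  return m;
}

// Connected-component labelling of a logical mask by flood fill.
// conn = 8 or 4; labels assigned in row-major scan order starting at 1.
// [[Rcpp::export]]
IntegerMatrix label_mask_cpp(LogicalMatrix mask, int conn) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int nnb = (conn == 8) ? 8 : 4;
  // for conn==4 use E, N, W, S only
  static const int DR4[4] = { 0, -1, 0, 1 };
  static const int DC4[4] = { 1, 0, -1, 0 };
  std::vector<int> stack;
  int next = 0;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (mask(r, c) != TRUE || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r * nc + c);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int cr = idx / nc, ccol = idx % nc;
        for (int k = 0; k < nnb; ++k) {
          int r2 = cr + (conn == 8 ? DR[k] : DR4[k]);
          int c2 = ccol + (conn == 8 ? DC[k] : DC4[k]);
          if (r2 < 0 || c2 < 0 || r2 >= nr || c2 >= nc) continue;
          if (mask(r2, c2) == TRUE && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 * nc + c2);
          }
        }
      }
    }
  }
  return lab;
}

// 8-neighbour foreground count for every pixel of a mask.
// [[Rcpp::export]]
IntegerMatrix neighbor_count_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      out(r, c) = (mask(r, c) == TRUE) ? nbcount(mask, r, c) : 0;
  return out;
}
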