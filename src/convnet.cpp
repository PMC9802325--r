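// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// 3x3 same-padding convolution kernels used by the classifier.  Activations
// are R arrays with dim (H, W, C, B), column-major; weights (3, 3, Cin, Cout).
// The convolution is computed as one GEMM per sample via im2col.

static void im2col3x3(const double *x, int H, int W, int Ci, arma::mat &M) {
  // M is (9*Ci) x (H*W); pixel j = r + c*H; kernel row = ci*9 + dx*3 + dy
  M.zeros();
  for (int ci = 0; ci < Ci; ++ci) {
    const double *xc = x + (size_t)ci * H * W;
    for (int dx = 0; dx < 3; ++dx) {
      for (int dy = 0; dy < 3; ++dy) {
        int row = ci * 9 + dx * 3 + dy;
        int orow = dy - 1, ocol = dx - 1;
        for (int c = 0; c < W; ++c) {
          int cs = c + ocol;
          if (cs < 0 || cs >= W) continue;
          int r0 = std::max(0, -orow), r1 = std::min(H, H - orow);
          const double *src = xc + (size_t)cs * H + r0 + orow;
          for (int r = r0; r < r1; ++r)
            M(row, r + (size_t)c * H) = src[r - r0];
        }
      }
    }
  }
}

static arma::mat weight_mat(const NumericVector &Wv, int Ci, int Co) {
  arma::mat Wm(Co, 9 * Ci);
  // Wv dim (3,3,Ci,Co): element (dy,dx,ci,co) at dy + dx*3 + ci*9 + co*9*Ci
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < Ci; ++ci)
      for (int dx = 0; dx < 3; ++dx)
        for (int dy = 0; dy < 3; ++dy)
          Wm(co, ci * 9 + dx * 3 + dy) =
            Wv[dy + dx * 3 + (size_t)ci * 9 + (size_t)co * 9 * Ci];
  return Wm;
}

// [[Rcpp::export]]
NumericVector conv3x3_fwd_cpp(NumericVector x, NumericVector W) {
  IntegerVector xd = x.attr("dim"), wd = W.attr("dim");
  int H = xd[0], Wd = xd[1], Ci = xd[2], B = xd[3], Co = wd[3];
  arma::mat Wm = weight_mat(W, Ci, Co);
  NumericVector y((R_xlen_t)H * Wd * Co * B);
  y.attr("dim") = IntegerVector::create(H, Wd, Co, B);
  arma::mat M(9 * Ci, (size_t)H * Wd);
  for (int b = 0; b < B; ++b) {
    const double *xb = x.begin() + (size_t)b * H * Wd * Ci;
    im2col3x3(xb, H, Wd, Ci, M);
    arma::mat Yb = Wm * M;  // Co x (H*W)
    double *yb = y.begin() + (size_t)b * H * Wd * Co;
    for (int co = 0; co < Co; ++co) {
      double *dst = yb + (size_t)co * H * Wd;
      for (size_t j = 0; j < (size_t)H * Wd; ++j) dst[j] = Yb(co, j);
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv3x3_bwd_cpp(NumericVector x, NumericVector W, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = W.attr("dim");
  int H = xd[0], Wd = xd[1], Ci = xd[2], B = xd[3], Co = wd[3];
  arma::mat Wm = weight_mat(W, Ci, Co);
  NumericVector gx((R_xlen_t)H * Wd * Ci * B);
  gx.attr("dim") = IntegerVector::create(H, Wd, Ci, B);
  arma::mat gWm(Co, 9 * Ci, arma::fill::zeros);
  arma::mat M(9 * Ci, (size_t)H * Wd);
  arma::mat Gy(Co, (size_t)H * Wd);
  for (int b = 0; b < B; ++b) {
    const double *xb = x.begin() + (size_t)b * H * Wd * Ci;
    const double *gyb = gy.begin() + (size_t)b * H * Wd * Co;
    im2col3x3(xb, H, Wd, Ci, M);
    for (int co = 0; co < Co; ++co) {
      const double *src = gyb + (size_t)co * H * Wd;
      for (size_t j = 0; j < (size_t)H * Wd; ++j) Gy(co, j) = src[j];
    }
    gWm += Gy * M.t();
    arma::mat Gcol = Wm.t() * Gy;  // (9*Ci) x (H*W)
    double *gxb = gx.begin() + (size_t)b * H * Wd * Ci;
    // col2im scatter-add
    for (int ci = 0; ci < Ci; ++ci) {
      double *gxc = gxb + (size_t)ci * H * Wd;
      for (int dx = 0; dx < 3; ++dx) {
        for (int dy = 0; dy < 3; ++dy) {
          int row = ci * 9 + dx * 3 + dy;
          int orow = dy - 1, ocol = dx - 1;
          for (int c = 0; c < Wd; ++c) {
            int cs = c + ocol;
            if (cs < 0 || cs >= Wd) continue;
            int r0 = std::max(0, -orow), r1 = std::min(H, H - orow);
            for (int r = r0; r < r1; ++r)
              gxc[(size_t)cs * H + r + orow] += Gcol(row, r + (size_t)c * H);
          }
        }
      }
    }
  }
  NumericVector gW((R_xlen_t)9 * Ci * Co);
  gW.attr("dim") = IntegerVector::create(3, 3, Ci, Co);
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < Ci; ++ci)
      for (int dx = 0; dx < 3; ++dx)
        for (int dy = 0; dy < 3; ++dy)
          gW[dy + dx * 3 + (size_t)ci * 9 + (size_t)co * 9 * Ci] =
            gWm(co, ci * 9 + dx * 3 + dy);
  return List::create(_["gx"] = gx, _["gW"] = gW);
}

// 2x2 max pooling with stride 2; returns pooled values and the 0-based linear
// index of each argmax into the input array (ties broken toward the
// upper-left, deterministically).
// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  IntegerVector idx(y.size());
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double *xp = x.begin() + ((size_t)b * C + c) * H * W;
      size_t base = ((size_t)b * C + c) * H * W;
      for (int cc = 0; cc < Wo; ++cc) {
        for (int rr = 0; rr < Ho; ++rr) {
          int r = 2 * rr, cl = 2 * cc;
          size_t i00 = (size_t)cl * H + r;
          size_t cand[4] = { i00, i00 + 1, i00 + H, i00 + H + 1 };
          size_t best = cand[0];
          for (int k = 1; k < 4; ++k)
            if (xp[cand[k]] > xp[best]) best = cand[k];
          // output element (rr, cc, c, b)
          size_t oi = (size_t)rr + (size_t)cc * Ho + ((size_t)b * C + c) * Ho * Wo;
          y[oi] = xp[best];
          idx[oi] = (int)(base + best);
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(NumericVector gy, IntegerVector idx,
                               IntegerVector xdim) {
  NumericVector gx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i]] += gy[i];
  return gx;
}
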