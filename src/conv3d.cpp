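// 3D convolution primitives for the dual-stream network.
// Feature maps are dense double arrays with dim (D, H, W, C), column-major.
// Conv weights have dim (k, k, k, Cin, Cout). All gradients are exact
// (validated by finite differences in the test suite).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// The convolution is computed as a sum over the k^3 kernel offsets of
// small GEMMs: Y (N x Cout) += Shift_o(X) (N x Cin) * W_o (Cin x Cout),
// where Shift_o(X) is the input translated by the offset with zero padding.
// This keeps the scratch buffer at N x Cin doubles regardless of kernel
// size, which matters for the full-resolution decoder levels.

// copy x translated by (dz, dy, dx) into S (N x C), zero-filled outside
static void shift_into(const double* x, arma::mat& S, int D, int H, int W,
                       int C, int dz, int dy, int dx) {
  const size_t N = (size_t)D * H * W;
  S.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + N * c;
    double* sc = S.colptr(c);
    for (int w = 0; w < W; ++w) {
      const int sw = w + dx;
      if (sw < 0 || sw >= W) continue;
      for (int h = 0; h < H; ++h) {
        const int sh = h + dy;
        if (sh < 0 || sh >= H) continue;
        const double* src = xc + (size_t)D * (sh + (size_t)H * sw);
        double* dst = sc + (size_t)D * (h + (size_t)H * w);
        const int d0 = std::max(0, -dz), d1 = std::min(D, D - dz);
        for (int d = d0; d < d1; ++d) dst[d] = src[d + dz];
      }
    }
  }
}

// scatter-add S (N x C) translated by the *reverse* of (dz, dy, dx) into gx
static void shift_back_add(const arma::mat& S, double* gx, int D, int H,
                           int W, int C, int dz, int dy, int dx) {
  const size_t N = (size_t)D * H * W;
  for (int c = 0; c < C; ++c) {
    double* gc = gx + N * c;
    const double* sc = S.colptr(c);
    for (int w = 0; w < W; ++w) {
      const int sw = w + dx;
      if (sw < 0 || sw >= W) continue;
      for (int h = 0; h < H; ++h) {
        const int sh = h + dy;
        if (sh < 0 || sh >= H) continue;
        double* dst = gc + (size_t)D * (sh + (size_t)H * sw);
        const double* src = sc + (size_t)D * (h + (size_t)H * w);
        const int d0 = std::max(0, -dz), d1 = std::min(D, D - dz);
        for (int d = d0; d < d1; ++d) dst[d + dz] += src[d];
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, NumericVector w,
                             NumericVector b, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const int k = wd[0], Cout = wd[4];
  if (wd[3] != C) stop("conv3d: input channels do not match weights");
  const size_t N = (size_t)D * H * W;
  const int k3 = k * k * k;
  arma::mat Y(N, Cout);
  for (int co = 0; co < Cout; ++co) Y.col(co).fill(b[co]);
  arma::mat S(N, C);
  for (int ow = 0; ow < k; ++ow)
    for (int oh = 0; oh < k; ++oh)
      for (int od = 0; od < k; ++od) {
        const int o = od + k * (oh + k * ow);
        // weight slice W_o: rows (o, o + k3, o + 2*k3, ...) of the
        // (k3*Cin) x Cout matrix -> gather into a Cin x Cout block
        arma::mat Wo(C, Cout);
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < C; ++ci)
            Wo(ci, co) = w[(size_t)o + (size_t)k3 * ci +
                           (size_t)k3 * C * co];
        if (k == 1) {
          const arma::mat X(const_cast<double*>(x.begin()), N, C, false,
                            true);
          Y += X * Wo;
        } else {
          shift_into(x.begin(), S, D, H, W, C, od - pad, oh - pad, ow - pad);
          Y += S * Wo;
        }
      }
  NumericVector y(Y.begin(), Y.end());
  y.attr("dim") = IntegerVector::create(D, H, W, Cout);
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const int k = wd[0], Cout = wd[4];
  const size_t N = (size_t)D * H * W;
  const int k3 = k * k * k;
  const arma::mat Gy(const_cast<double*>(gy.begin()), N, Cout, false, true);
  arma::rowvec Gb = arma::sum(Gy, 0);
  NumericVector gx((R_xlen_t)(N * C)), gw(w.size());
  gx.attr("dim") = IntegerVector::create(D, H, W, C);
  gw.attr("dim") = wd;
  arma::mat S(N, C);
  for (int ow = 0; ow < k; ++ow)
    for (int oh = 0; oh < k; ++oh)
      for (int od = 0; od < k; ++od) {
        const int o = od + k * (oh + k * ow);
        arma::mat Wo(C, Cout);
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < C; ++ci)
            Wo(ci, co) = w[(size_t)o + (size_t)k3 * ci +
                           (size_t)k3 * C * co];
        arma::mat Gwo;
        if (k == 1) {
          const arma::mat X(const_cast<double*>(x.begin()), N, C, false,
                            true);
          Gwo = X.t() * Gy;                       // Cin x Cout
          arma::mat GS = Gy * Wo.t();             // N x Cin
          double* gp = gx.begin();
          const double* sp = GS.memptr();
          for (size_t i = 0; i < N * C; ++i) gp[i] += sp[i];
        } else {
          shift_into(x.begin(), S, D, H, W, C, od - pad, oh - pad, ow - pad);
          Gwo = S.t() * Gy;
          arma::mat GS = Gy * Wo.t();
          shift_back_add(GS, gx.begin(), D, H, W, C, od - pad, oh - pad,
                         ow - pad);
        }
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < C; ++ci)
            gw[(size_t)o + (size_t)k3 * ci + (size_t)k3 * C * co] =
                Gwo(ci, co);
      }
  NumericVector gb(Gb.begin(), Gb.end());
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Transpose convolution, kernel 2, stride 2: each input voxel writes one
// non-overlapping 2x2x2 output block. Doubles every spatial dimension.
// [[Rcpp::export]]
NumericVector cpp_upconv3d_fwd(NumericVector x, NumericVector w,
                               NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const int Cout = wd[4];
  const int D2 = 2 * D, H2 = 2 * H, W2 = 2 * W;
  const size_t N = (size_t)D * H * W, N2 = (size_t)D2 * H2 * W2;
  NumericVector y(N2 * Cout);
  for (int co = 0; co < Cout; ++co) {
    double* yc = y.begin() + N2 * co;
    for (size_t i = 0; i < N2; ++i) yc[i] = b[co];
    for (int ci = 0; ci < C; ++ci) {
      const double* xc = x.begin() + N * ci;
      const double* wk = w.begin() + 8 * ((size_t)ci + (size_t)C * co);
      for (int ww = 0; ww < W; ++ww)
        for (int hh = 0; hh < H; ++hh)
          for (int dd = 0; dd < D; ++dd) {
            const double xv = xc[dd + (size_t)D * (hh + (size_t)H * ww)];
            if (xv == 0.0) continue;
            for (int ow = 0; ow < 2; ++ow)
              for (int oh = 0; oh < 2; ++oh)
                for (int od = 0; od < 2; ++od)
                  yc[(2 * dd + od) +
                     (size_t)D2 * ((2 * hh + oh) + (size_t)H2 * (2 * ww + ow))] +=
                      xv * wk[od + 2 * (oh + 2 * ow)];
          }
    }
  }
  y.attr("dim") = IntegerVector::create(D2, H2, W2, Cout);
  return y;
}

// [[Rcpp::export]]
List cpp_upconv3d_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const int Cout = wd[4];
  const int D2 = 2 * D, H2 = 2 * H, W2 = 2 * W;
  const size_t N = (size_t)D * H * W, N2 = (size_t)D2 * H2 * W2;
  NumericVector gx(N * C), gw(w.size()), gb(Cout);
  for (int co = 0; co < Cout; ++co) {
    const double* gyc = gy.begin() + N2 * co;
    double acc = 0.0;
    for (size_t i = 0; i < N2; ++i) acc += gyc[i];
    gb[co] = acc;
    for (int ci = 0; ci < C; ++ci) {
      const double* xc = x.begin() + N * ci;
      double* gxc = gx.begin() + N * ci;
      const double* wk = w.begin() + 8 * ((size_t)ci + (size_t)C * co);
      double* gwk = gw.begin() + 8 * ((size_t)ci + (size_t)C * co);
      for (int ww = 0; ww < W; ++ww)
        for (int hh = 0; hh < H; ++hh)
          for (int dd = 0; dd < D; ++dd) {
            const size_t xi = dd + (size_t)D * (hh + (size_t)H * ww);
            const double xv = xc[xi];
            double g = 0.0;
            for (int ow = 0; ow < 2; ++ow)
              for (int oh = 0; oh < 2; ++oh)
                for (int od = 0; od < 2; ++od) {
                  const double gv =
                      gyc[(2 * dd + od) +
                          (size_t)D2 *
                              ((2 * hh + oh) + (size_t)H2 * (2 * ww + ow))];
                  g += gv * wk[od + 2 * (oh + 2 * ow)];
                  gwk[od + 2 * (oh + 2 * ow)] += gv * xv;
                }
            gxc[xi] += g;
          }
    }
  }
  gx.attr("dim") = IntegerVector::create(D, H, W, C);
  gw.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Max pooling, kernel 2, stride 2. Spatial dims must be even. Returns the
// pooled map and the 1-based linear argmax indices into the input (ties to
// the first element in scan order, deterministically).
// [[Rcpp::export]]
List cpp_maxpool3d_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3];
  if (D % 2 || H % 2 || W % 2) stop("maxpool3d: odd spatial dimension");
  const int D2 = D / 2, H2 = H / 2, W2 = W / 2;
  const size_t N = (size_t)D * H * W, N2 = (size_t)D2 * H2 * W2;
  NumericVector y(N2 * C);
  IntegerVector idx(N2 * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + N * c;
    for (int ww = 0; ww < W2; ++ww)
      for (int hh = 0; hh < H2; ++hh)
        for (int dd = 0; dd < D2; ++dd) {
          double best = -std::numeric_limits<double>::infinity();
          size_t besti = 0;
          for (int ow = 0; ow < 2; ++ow)
            for (int oh = 0; oh < 2; ++oh)
              for (int od = 0; od < 2; ++od) {
                const size_t i =
                    (2 * dd + od) +
                    (size_t)D * ((2 * hh + oh) + (size_t)H * (2 * ww + ow));
                if (xc[i] > best) { best = xc[i]; besti = i; }
              }
          const size_t o = dd + (size_t)D2 * (hh + (size_t)H2 * ww) + N2 * c;
          y[o] = best;
          idx[o] = (int)(besti + N * c) + 1;
        }
  }
  y.attr("dim") = IntegerVector::create(D2, H2, W2, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bwd(NumericVector gy, IntegerVector idx,
                                IntegerVector xdim) {
  const size_t N = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(N);
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i] - 1] += gy[i];
  gx.attr("dim") = xdim;
  return gx;
}
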