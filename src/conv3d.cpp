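// Patch extraction/scatter primitives for the pseudo-CT encoder-decoder.
// Convolutions are evaluated as im2col + BLAS matrix multiply on the R side;
// the two kernels here only move data. Layout follows R column-major arrays:
// x has dim (D, H, W, C); the patch matrix has one row per output voxel
// (od fastest) and one column per kernel tap, ordered (kd, kh, kw, ci) to
// match matrix(w, k^3*Cin, Cout) for weights of dim (k, k, k, Cin, Cout).
#include <Rcpp.h>
using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// valid output index range along one axis: id = o*s + koff - pad in [0, n-1]
static inline void orange(int n, int no, int koff, int s, int pad,
                          int &lo, int &hi) {
  int num = pad - koff;
  lo = (num <= 0) ? 0 : (num + s - 1) / s;
  hi = (n - 1 - koff + pad) / s;
  if (hi > no - 1) hi = no - 1;
}

// [[Rcpp::export]]
NumericMatrix im2col3d(NumericVector x, IntegerVector xdim,
                       int k, int stride, int pad) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], Ci = xdim[3];
  const int oD = out_size(D, k, stride, pad);
  const int oH = out_size(H, k, stride, pad);
  const int oW = out_size(W, k, stride, pad);
  const R_xlen_t N = R_xlen_t(oD) * oH * oW;
  const R_xlen_t M = R_xlen_t(k) * k * k * Ci;
  NumericMatrix P(N, M);
  const double *px = x.begin();
  double *pp = P.begin();
  const R_xlen_t xc = R_xlen_t(D) * H * W;
  for (int ci = 0; ci < Ci; ++ci) {
    const double *x0 = px + xc * ci;
    for (int kw = 0; kw < k; ++kw) {
      int wlo, whi; orange(W, oW, kw, stride, pad, wlo, whi);
      for (int kh = 0; kh < k; ++kh) {
        int hlo, hhi; orange(H, oH, kh, stride, pad, hlo, hhi);
        for (int kd = 0; kd < k; ++kd) {
          int dlo, dhi; orange(D, oD, kd, stride, pad, dlo, dhi);
          const R_xlen_t col = kd + R_xlen_t(k) * (kh + R_xlen_t(k) * (kw + R_xlen_t(k) * ci));
          double *pc = pp + N * col;
          for (int ow = wlo; ow <= whi; ++ow) {
            const int iw = ow * stride + kw - pad;
            for (int oh = hlo; oh <= hhi; ++oh) {
              const int ih = oh * stride + kh - pad;
              const double *xp = x0 + R_xlen_t(D) * (ih + (R_xlen_t)H * iw) +
                R_xlen_t(dlo) * stride + kd - pad;
              double *dst = pc + (R_xlen_t(ow) * oH + oh) * oD + dlo;
              for (int od = dlo; od <= dhi; ++od, xp += stride, ++dst)
                *dst = *xp;
            }
          }
        }
      }
    }
  }
  return P;
}

// adjoint of im2col3d: scatter-add patch values back onto the input grid
// [[Rcpp::export]]
NumericVector col2im3d(NumericMatrix P, IntegerVector xdim,
                       int k, int stride, int pad) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], Ci = xdim[3];
  const int oD = out_size(D, k, stride, pad);
  const int oH = out_size(H, k, stride, pad);
  const int oW = out_size(W, k, stride, pad);
  const R_xlen_t N = R_xlen_t(oD) * oH * oW;
  NumericVector x(R_xlen_t(D) * H * W * Ci);
  double *px = x.begin();
  const double *pp = P.begin();
  const R_xlen_t xc = R_xlen_t(D) * H * W;
  for (int ci = 0; ci < Ci; ++ci) {
    double *x0 = px + xc * ci;
    for (int kw = 0; kw < k; ++kw) {
      int wlo, whi; orange(W, oW, kw, stride, pad, wlo, whi);
      for (int kh = 0; kh < k; ++kh) {
        int hlo, hhi; orange(H, oH, kh, stride, pad, hlo, hhi);
        for (int kd = 0; kd < k; ++kd) {
          int dlo, dhi; orange(D, oD, kd, stride, pad, dlo, dhi);
          const R_xlen_t col = kd + R_xlen_t(k) * (kh + R_xlen_t(k) * (kw + R_xlen_t(k) * ci));
          const double *pc = pp + N * col;
          for (int ow = wlo; ow <= whi; ++ow) {
            const int iw = ow * stride + kw - pad;
            for (int oh = hlo; oh <= hhi; ++oh) {
              const int ih = oh * stride + kh - pad;
              double *xp = x0 + R_xlen_t(D) * (ih + (R_xlen_t)H * iw) +
                R_xlen_t(dlo) * stride + kd - pad;
              const double *src = pc + (R_xlen_t(ow) * oH + oh) * oD + dlo;
              for (int od = dlo; od <= dhi; ++od, xp += stride, ++src)
                *xp += *src;
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(D, H, W, Ci);
  return x;
}

// direct convolution forward: output volumes are small and stay cache-hot,
// which beats materializing the patch matrix at these window sizes
// [[Rcpp::export]]
NumericVector conv3d_fwd(NumericVector x, IntegerVector xdim,
                         NumericVector w, IntegerVector wdim,
                         NumericVector bias, int stride, int pad) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], Ci = xdim[3];
  const int k = wdim[0], Co = wdim[4];
  const int oD = out_size(D, k, stride, pad);
  const int oH = out_size(H, k, stride, pad);
  const int oW = out_size(W, k, stride, pad);
  NumericVector out(R_xlen_t(oD) * oH * oW * Co);
  double *po = out.begin();
  const double *px = x.begin(), *pw = w.begin(), *pb = bias.begin();
  const R_xlen_t xc = R_xlen_t(D) * H * W;
  const R_xlen_t oc = R_xlen_t(oD) * oH * oW;
  for (int co = 0; co < Co; ++co) {
    double *o0 = po + oc * co;
    const double bv = pb[co];
    for (R_xlen_t i = 0; i < oc; ++i) o0[i] = bv;
    for (int ci = 0; ci < Ci; ++ci) {
      const double *x0 = px + xc * ci;
      for (int kw = 0; kw < k; ++kw) {
        int wlo, whi; orange(W, oW, kw, stride, pad, wlo, whi);
        for (int kh = 0; kh < k; ++kh) {
          int hlo, hhi; orange(H, oH, kh, stride, pad, hlo, hhi);
          for (int kd = 0; kd < k; ++kd) {
            int dlo, dhi; orange(D, oD, kd, stride, pad, dlo, dhi);
            const double wv =
              pw[kd + k * (kh + k * (kw + k * (ci + (R_xlen_t)Ci * co)))];
            if (wv == 0.0) continue;
            for (int ow = wlo; ow <= whi; ++ow) {
              const int iw = ow * stride + kw - pad;
              for (int oh = hlo; oh <= hhi; ++oh) {
                const int ih = oh * stride + kh - pad;
                const double *xp = x0 + R_xlen_t(D) * (ih + (R_xlen_t)H * iw) +
                  R_xlen_t(dlo) * stride + kd - pad;
                double *op = o0 + R_xlen_t(oD) * (oh + (R_xlen_t)oH * ow) + dlo;
                if (stride == 1)
                  for (int od = dlo; od <= dhi; ++od, ++xp, ++op)
                    *op += wv * (*xp);
                else
                  for (int od = dlo; od <= dhi; ++od, xp += stride, ++op)
                    *op += wv * (*xp);
              }
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(oD, oH, oW, Co);
  return out;
}

// direct gradient w.r.t. the convolution input (also the forward pass of the
// transposed upsampling convolution)
// [[Rcpp::export]]
NumericVector conv3d_bwd_x(NumericVector gout, IntegerVector odim,
                           NumericVector w, IntegerVector wdim,
                           IntegerVector xdim, int stride, int pad) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], Ci = xdim[3];
  const int oD = odim[0], oH = odim[1], oW = odim[2], Co = odim[3];
  const int k = wdim[0];
  NumericVector gx(R_xlen_t(D) * H * W * Ci);
  double *pgx = gx.begin();
  const double *pg = gout.begin(), *pw = w.begin();
  const R_xlen_t xc = R_xlen_t(D) * H * W;
  const R_xlen_t oc = R_xlen_t(oD) * oH * oW;
  for (int co = 0; co < Co; ++co) {
    const double *g0 = pg + oc * co;
    for (int ci = 0; ci < Ci; ++ci) {
      double *x0 = pgx + xc * ci;
      for (int kw = 0; kw < k; ++kw) {
        int wlo, whi; orange(W, oW, kw, stride, pad, wlo, whi);
        for (int kh = 0; kh < k; ++kh) {
          int hlo, hhi; orange(H, oH, kh, stride, pad, hlo, hhi);
          for (int kd = 0; kd < k; ++kd) {
            int dlo, dhi; orange(D, oD, kd, stride, pad, dlo, dhi);
            const double wv =
              pw[kd + k * (kh + k * (kw + k * (ci + (R_xlen_t)Ci * co)))];
            if (wv == 0.0) continue;
            for (int ow = wlo; ow <= whi; ++ow) {
              const int iw = ow * stride + kw - pad;
              for (int oh = hlo; oh <= hhi; ++oh) {
                const int ih = oh * stride + kh - pad;
                double *xp = x0 + R_xlen_t(D) * (ih + (R_xlen_t)H * iw) +
                  R_xlen_t(dlo) * stride + kd - pad;
                const double *gp = g0 + R_xlen_t(oD) * (oh + (R_xlen_t)oH * ow) + dlo;
                if (stride == 1)
                  for (int od = dlo; od <= dhi; ++od, ++xp, ++gp)
                    *xp += wv * (*gp);
                else
                  for (int od = dlo; od <= dhi; ++od, xp += stride, ++gp)
                    *xp += wv * (*gp);
              }
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(D, H, W, Ci);
  return gx;
}
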