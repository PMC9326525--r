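// im2col / col2im gather-scatter kernels for the convolution engine.
// Layout is the engine's channels-last order: x is (H, W, N, C) flattened
// column-major; the column matrix is (ho*wo*N) x (kh*kw*C) with column
// blocks ordered offset-major (channels within an offset), matching the
// reshaped weight matrix.  1-D convolutions reuse the same kernels with
// W = 1, kw = 1.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col2d_cpp(NumericVector x, int H, int W, int N, int C,
                           int kh, int kw, int stride, int ph, int pw,
                           int ho, int wo) {
  const R_xlen_t M = (R_xlen_t)ho * wo * N;
  NumericMatrix out(M, (R_xlen_t)kh * kw * C);
  const double* px = x.begin();
  double* po = out.begin();
  const R_xlen_t planeHW = (R_xlen_t)H * W;
  for (int i = 0; i < kh; ++i) {
    for (int j = 0; j < kw; ++j) {
      const int o = i * kw + j;
      for (int c = 0; c < C; ++c) {
        double* dcol = po + ((R_xlen_t)o * C + c) * M;
        const double* splane = px + (R_xlen_t)c * planeHW * N;
        for (int n = 0; n < N; ++n) {
          const double* sn = splane + (R_xlen_t)n * planeHW;
          for (int xo = 0; xo < wo; ++xo) {
            const int sx = xo * stride + j - pw;
            double* d = dcol + (R_xlen_t)n * ho * wo + (R_xlen_t)xo * ho;
            if (sx < 0 || sx >= W) {
              for (int yo = 0; yo < ho; ++yo) d[yo] = 0.0;
              continue;
            }
            const double* scol = sn + (R_xlen_t)sx * H;
            for (int yo = 0; yo < ho; ++yo) {
              const int sy = yo * stride + i - ph;
              d[yo] = (sy < 0 || sy >= H) ? 0.0 : scol[sy];
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im2d_cpp(NumericMatrix dXc, int H, int W, int N, int C,
                           int kh, int kw, int stride, int ph, int pw,
                           int ho, int wo) {
  const R_xlen_t M = (R_xlen_t)ho * wo * N;
  NumericVector dx((R_xlen_t)H * W * N * C);
  const double* ps = dXc.begin();
  double* pd = dx.begin();
  const R_xlen_t planeHW = (R_xlen_t)H * W;
  for (int i = 0; i < kh; ++i) {
    for (int j = 0; j < kw; ++j) {
      const int o = i * kw + j;
      for (int c = 0; c < C; ++c) {
        const double* scol = ps + ((R_xlen_t)o * C + c) * M;
        double* dplane = pd + (R_xlen_t)c * planeHW * N;
        for (int n = 0; n < N; ++n) {
          double* dn = dplane + (R_xlen_t)n * planeHW;
          for (int xo = 0; xo < wo; ++xo) {
            const int sx = xo * stride + j - pw;
            if (sx < 0 || sx >= W) continue;
            const double* s = scol + (R_xlen_t)n * ho * wo +
              (R_xlen_t)xo * ho;
            double* dcol = dn + (R_xlen_t)sx * H;
            for (int yo = 0; yo < ho; ++yo) {
              const int sy = yo * stride + i - ph;
              if (sy >= 0 && sy < H) dcol[sy] += s[yo];
            }
          }
        }
      }
    }
  }
  return dx;
}
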