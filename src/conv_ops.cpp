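#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Lower a (H x W x C) image into a (k*k*C) x (H*W) patch matrix for
// stride-1 "same" convolution with zero padding. Column c of the result
// holds the k x k x C neighbourhood of output pixel c (column-major pixel
// order, i + H*j). Row order is (ki, kj, channel).
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int k, int pad) {
  const int HW = H * W;
  const int rows = k * k * C;
  NumericMatrix out(rows, HW);
  const double* px = x.begin();
  double* po = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * kj + k * k * c;
        const int imin = std::max(0, pad - ki);
        const int imax = std::min(H, H + pad - ki);
        for (int j = 0; j < W; ++j) {
          const int sj = j + kj - pad;
          if (sj < 0 || sj >= W) continue;
          const double* src = px + (size_t)c * HW + (size_t)sj * H + (ki - pad);
          double* dst = po + r;
          const size_t base = (size_t)rows * ((size_t)H * j);
          for (int i = imin; i < imax; ++i)
            dst[base + (size_t)rows * i] = src[i];
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_cpp: scatter-add a (k*k*C) x (H*W) patch matrix back
// into an H x W x C image. Used for the gradient with respect to the
// convolution input.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int k, int pad) {
  const int HW = H * W;
  const int rows = k * k * C;
  NumericVector out((size_t)HW * C);  // zero-initialised
  double* po = out.begin();
  const double* pc = cols.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * kj + k * k * c;
        const int imin = std::max(0, pad - ki);
        const int imax = std::min(H, H + pad - ki);
        for (int j = 0; j < W; ++j) {
          const int sj = j + kj - pad;
          if (sj < 0 || sj >= W) continue;
          double* dst = po + (size_t)c * HW + (size_t)sj * H + (ki - pad);
          const double* src = pc + r;
          const size_t base = (size_t)rows * ((size_t)H * j);
          for (int i = imin; i < imax; ++i)
            dst[i] += src[base + (size_t)rows * i];
        }
      }
    }
  }
  return out;
}
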