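#include <Rcpp.h>
using namespace Rcpp;

// Patch extraction for strided 2-D convolution on a batch of images.
//
// x is an [H, W, C, N] array (R column-major order) flattened to a vector.
// The result has one column per output position per sample, ordered
// (row, col, sample), and one row per patch element, ordered (kh, kw, c) so
// that a column is the column-major flattening of the [k, k, C] patch.

// [[Rcpp::export]]
NumericMatrix im2col_batch(NumericVector x, int H, int W, int C, int N,
                           int k, int stride, int pad, int oh, int ow) {
  NumericMatrix out(C * k * k, oh * ow * N);
  const double *px = x.begin();
  double *po = out.begin();
  const int nrow = C * k * k;
  for (int n = 0; n < N; ++n) {
    for (int j = 0; j < ow; ++j) {
      for (int i = 0; i < oh; ++i) {
        const R_xlen_t col = (R_xlen_t)i + (R_xlen_t)oh * j + (R_xlen_t)oh * ow * n;
        double *pc = po + col * nrow;
        const int h0 = i * stride - pad, w0 = j * stride - pad;
        for (int c = 0; c < C; ++c) {
          const double *plane = px + (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
          for (int kw = 0; kw < k; ++kw) {
            const int w = w0 + kw;
            for (int kh = 0; kh < k; ++kh) {
              const int h = h0 + kh;
              double v = 0.0;
              if (h >= 0 && h < H && w >= 0 && w < W)
                v = plane[h + (R_xlen_t)H * w];
              pc[kh + k * (kw + k * c)] = v;
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_batch: scatter-add patch columns back into an
// [H, W, C, N] array. Used for conv backward-data and transposed-conv
// forward passes.

// [[Rcpp::export]]
NumericVector col2im_batch(NumericMatrix cols, int H, int W, int C, int N,
                           int k, int stride, int pad, int oh, int ow) {
  NumericVector x((R_xlen_t)H * W * C * N);
  double *px = x.begin();
  const double *po = cols.begin();
  const int nrow = C * k * k;
  for (int n = 0; n < N; ++n) {
    for (int j = 0; j < ow; ++j) {
      for (int i = 0; i < oh; ++i) {
        const R_xlen_t col = (R_xlen_t)i + (R_xlen_t)oh * j + (R_xlen_t)oh * ow * n;
        const double *pc = po + col * nrow;
        const int h0 = i * stride - pad, w0 = j * stride - pad;
        for (int c = 0; c < C; ++c) {
          double *plane = px + (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
          for (int kw = 0; kw < k; ++kw) {
            const int w = w0 + kw;
            if (w < 0 || w >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int h = h0 + kh;
              if (h < 0 || h >= H) continue;
              plane[h + (R_xlen_t)H * w] += pc[kh + k * (kw + k * c)];
            }
          }
        }
      }
    }
  }
  return x;
}
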