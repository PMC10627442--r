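// im2col / col2im kernels for the same-padded, stride-1 correlation
// convolutions. Feature maps are (H, W, B, C) column-major arrays; the
// column matrix has one row per (h, w, b) position and k*k*C columns in
// (channel fastest, kernel column, kernel row) order, matching
// flattenKernel() on the R side. Padding is (k-1)/2 on top/left and the
// remainder on bottom/right, so even kernels anchor top-left.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int B, int C,
                         int k) {
  const int pt = (k - 1) / 2;
  const R_xlen_t n = (R_xlen_t)H * W * B;
  NumericMatrix col(n, (R_xlen_t)k * k * C);
  const double* xp = x.begin();
  double* cp = col.begin();
  for (int a = 0; a < k; ++a) {
    const int da = a - pt;
    for (int bb = 0; bb < k; ++bb) {
      const int db = bb - pt;
      const int o = a * k + bb;
      for (int c = 0; c < C; ++c) {
        double* dst = cp + ((R_xlen_t)o * C + c) * n;
        const double* src = xp + (R_xlen_t)c * n;
        for (int b = 0; b < B; ++b) {
          const R_xlen_t plane = (R_xlen_t)H * W * b;
          for (int w = 0; w < W; ++w) {
            double* d2 = dst + plane + (R_xlen_t)H * w;
            const int ws = w + db;
            if (ws < 0 || ws >= W) {
              for (int h = 0; h < H; ++h) d2[h] = 0.0;
              continue;
            }
            const double* s2 = src + plane + (R_xlen_t)H * ws;
            const int h0 = std::max(0, -da), h1 = std::min(H, H - da);
            for (int h = 0; h < h0; ++h) d2[h] = 0.0;
            for (int h = h0; h < h1; ++h) d2[h] = s2[h + da];
            for (int h = h1; h < H; ++h) d2[h] = 0.0;
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dcol, int H, int W, int B, int C,
                         int k) {
  const int pt = (k - 1) / 2;
  const R_xlen_t n = (R_xlen_t)H * W * B;
  NumericVector dx((R_xlen_t)n * C);  // zero-initialized
  const double* cp = dcol.begin();
  double* xp = dx.begin();
  for (int a = 0; a < k; ++a) {
    const int da = a - pt;
    for (int bb = 0; bb < k; ++bb) {
      const int db = bb - pt;
      const int o = a * k + bb;
      for (int c = 0; c < C; ++c) {
        const double* src = cp + ((R_xlen_t)o * C + c) * n;
        double* dst = xp + (R_xlen_t)c * n;
        for (int b = 0; b < B; ++b) {
          const R_xlen_t plane = (R_xlen_t)H * W * b;
          for (int w = 0; w < W; ++w) {
            const int ws = w + db;
            if (ws < 0 || ws >= W) continue;
            const double* s2 = src + plane + (R_xlen_t)H * w;
            double* d2 = dst + plane + (R_xlen_t)H * ws;
            const int h0 = std::max(0, -da), h1 = std::min(H, H - da);
            for (int h = h0; h < h1; ++h) d2[h + da] += s2[h];
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, B, C);
  return dx;
}
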