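#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Patch-matrix assembly for 3x3 same-padding convolution on a channel-first
// (C, H, W, N) tensor: returns the (9C x HWN) im2col matrix. Offset blocks
// are ordered column-offset-major (dx outer, dy inner), matching the kernel
// layout used by the R layers.
// [[Rcpp::export]]
NumericMatrix im2col3_cpp(NumericVector x, IntegerVector dims) {
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  const int HWN = H * W * N;
  const int nrow = 9 * C;
  NumericMatrix P(nrow, HWN);
  const double* xp = x.begin();
  double* pp = P.begin();
  for (int n = 0; n < N; ++n) {
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const size_t col = (size_t)h + (size_t)H * (w + (size_t)W * n);
        double* pcol = pp + col * nrow;
        int k = 0;
        for (int dx = -1; dx <= 1; ++dx) {
          const int xx = w + dx;
          for (int dy = -1; dy <= 1; ++dy, ++k) {
            const int yy = h + dy;
            if (xx >= 0 && xx < W && yy >= 0 && yy < H) {
              const double* src = xp + (size_t)C * (yy + (size_t)H * (xx + (size_t)W * n));
              std::memcpy(pcol + (size_t)k * C, src, C * sizeof(double));
            }
          }
        }
      }
    }
  }
  return P;
}
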