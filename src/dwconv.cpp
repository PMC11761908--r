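// Depthwise 3x3 convolution kernels (stride 1, zero padding 1) on
// H x W x C x N column-major arrays, forward and backward. Loops are
// offset-major with precomputed valid ranges so the innermost loop is a
// branch-free fused multiply-add along contiguous memory. These are the
// innermost loops of the network; everything else stays in R on top of BLAS.
#include <Rcpp.h>
using namespace Rcpp;

// y[i,j,c,n] = sum_{di,dj in {-1,0,1}} x[i+di, j+dj, c, n] * k[di+1, dj+1, c]
// [[Rcpp::export]]
NumericVector dwconv_fwd_cpp(NumericVector x, NumericVector kd) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector y(x.size());
  y.attr("dim") = d;
  const double* px = x.begin();
  const double* pk = kd.begin();
  double* py = y.begin();
  for (int n = 0; n < N; n++) {
    for (int c = 0; c < C; c++) {
      const double* xs = px + ((size_t)n * C + c) * H * W;
      double* ys = py + ((size_t)n * C + c) * H * W;
      const double* k = pk + (size_t)c * 9;
      for (int dj = -1; dj <= 1; dj++) {
        const int j0 = dj < 0 ? 1 : 0;
        const int j1 = dj > 0 ? W - 1 : W;
        for (int di = -1; di <= 1; di++) {
          const int i0 = di < 0 ? 1 : 0;
          const int i1 = di > 0 ? H - 1 : H;
          const double kv = k[(dj + 1) * 3 + (di + 1)];
          if (kv == 0.0) continue;
          for (int j = j0; j < j1; j++) {
            const double* xcol = xs + (size_t)(j + dj) * H + di;
            double* ycol = ys + (size_t)j * H;
            for (int i = i0; i < i1; i++) ycol[i] += kv * xcol[i];
          }
        }
      }
    }
  }
  return y;
}

// Gradients of the same operation: dx[i+di, j+dj] += dy[i,j] * k[di,dj] and
// dk[di,dj,c] = sum_{i,j,n} x[i+di, j+dj, c, n] * dy[i,j,c,n].
// [[Rcpp::export]]
List dwconv_bwd_cpp(NumericVector x, NumericVector kd, NumericVector dy) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector dx(x.size());
  dx.attr("dim") = d;
  NumericVector dk(9 * (size_t)C);
  dk.attr("dim") = IntegerVector::create(3, 3, C);
  const double* px = x.begin();
  const double* pk = kd.begin();
  const double* pdy = dy.begin();
  double* pdx = dx.begin();
  double* pdk = dk.begin();
  for (int n = 0; n < N; n++) {
    for (int c = 0; c < C; c++) {
      const size_t off = ((size_t)n * C + c) * H * W;
      const double* xs = px + off;
      const double* gs = pdy + off;
      double* dxs = pdx + off;
      double* dkc = pdk + (size_t)c * 9;
      const double* k = pk + (size_t)c * 9;
      for (int dj = -1; dj <= 1; dj++) {
        const int j0 = dj < 0 ? 1 : 0;
        const int j1 = dj > 0 ? W - 1 : W;
        for (int di = -1; di <= 1; di++) {
          const int i0 = di < 0 ? 1 : 0;
          const int i1 = di > 0 ? H - 1 : H;
          const double kv = k[(dj + 1) * 3 + (di + 1)];
          double acc = 0.0;
          for (int j = j0; j < j1; j++) {
            const double* gcol = gs + (size_t)j * H;
            const double* xcol = xs + (size_t)(j + dj) * H + di;
            double* dxcol = dxs + (size_t)(j + dj) * H + di;
            for (int i = i0; i < i1; i++) {
              const double g = gcol[i];
              dxcol[i] += g * kv;
              acc += g * xcol[i];
            }
          }
          dkc[(dj + 1) * 3 + (di + 1)] += acc;
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dkd"] = dk);
}
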