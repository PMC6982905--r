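#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Images are numeric matrices in row-major R convention: [y, x], gray 0..255.
// All borders are handled by replicating the edge pixel.

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Direct 2-D convolution with replicate borders. Kernel must have odd sides.
// [[Rcpp::export(name = ".conv2_replicate")]]
NumericMatrix conv2_replicate(NumericMatrix img, NumericMatrix kernel) {
  int h = img.nrow(), w = img.ncol();
  int kh = kernel.nrow(), kw = kernel.ncol();
  if (kh % 2 == 0 || kw % 2 == 0) stop("kernel sides must be odd");
  int ry = kh / 2, rx = kw / 2;
  NumericMatrix out(h, w);
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) {
      double acc = 0.0;
      for (int j = -rx; j <= rx; ++j) {
        int xx = clampi(x + j, 0, w - 1);
        for (int i = -ry; i <= ry; ++i) {
          int yy = clampi(y + i, 0, h - 1);
          acc += img(yy, xx) * kernel(i + ry, j + rx);
        }
      }
      out(y, x) = acc;
    }
  }
  return out;
}

// Bilateral filter over a circular neighbourhood of the given diameter.
// Spatial weights are precomputed; range weights use a lookup table indexed
// by rounded absolute gray difference (inputs are 8-bit scale, 0..255).
// [[Rcpp::export(name = ".bilateral_replicate")]]
NumericMatrix bilateral_replicate(NumericMatrix img, int diameter,
                                  double sigma_color, double sigma_space) {
  if (diameter < 1) stop("diameter must be >= 1");
  if (sigma_color <= 0 || sigma_space <= 0) stop("sigmas must be positive");
  int h = img.nrow(), w = img.ncol();
  int r = diameter / 2;
  if (r < 1) r = 1;

  // circular window offsets and spatial weights
  std::vector<int> dx, dy;
  std::vector<double> sw;
  double gs = -0.5 / (sigma_space * sigma_space);
  for (int j = -r; j <= r; ++j)
    for (int i = -r; i <= r; ++i) {
      double d2 = (double)i * i + (double)j * j;
      if (d2 > (double)r * r) continue;
      dx.push_back(j);
      dy.push_back(i);
      sw.push_back(std::exp(d2 * gs));
    }
  int K = (int)dx.size();

  // range-weight LUT on integer gray differences
  double gc = -0.5 / (sigma_color * sigma_color);
  std::vector<double> lut(512);
  for (int d = 0; d < 512; ++d) lut[d] = std::exp((double)d * d * gc);

  // flat offsets for the interior fast path (column-major storage)
  std::vector<int> off(K);
  for (int k = 0; k < K; ++k) off[k] = dy[k] + dx[k] * h;

  NumericMatrix out(h, w);
  const double *p = REAL(img);
  double *q = REAL(out);
  for (int x = 0; x < w; ++x) {
    bool xin = (x >= r && x < w - r);
    for (int y = 0; y < h; ++y) {
      int base = y + x * h;
      double c = p[base];
      double num = 0.0, den = 0.0;
      if (xin && y >= r && y < h - r) {
        for (int k = 0; k < K; ++k) {
          double v = p[base + off[k]];
          int d = (int)(std::fabs(v - c) + 0.5);
          if (d > 511) d = 511;
          double wgt = sw[k] * lut[d];
          num += wgt * v;
          den += wgt;
        }
      } else {
        for (int k = 0; k < K; ++k) {
          int xx = clampi(x + dx[k], 0, w - 1);
          int yy = clampi(y + dy[k], 0, h - 1);
          double v = p[yy + xx * h];
          int d = (int)(std::fabs(v - c) + 0.5);
          if (d > 511) d = 511;
          double wgt = sw[k] * lut[d];
          num += wgt * v;
          den += wgt;
        }
      }
      q[base] = num / den;
    }
  }
  return out;
}
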