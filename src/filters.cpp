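#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// All windowed filters replicate edge pixels outside the image.
// Integer outputs are rounded half-up (floor(x + 0.5)) for determinism.

static inline int clampi(int i, int n) { return i < 0 ? 0 : (i >= n ? n - 1 : i); }
static inline double half_up(double x) { return std::floor(x + 0.5); }

// [[Rcpp::export]]
NumericMatrix cpp_mean_filter(NumericMatrix X, int radius, bool round_int) {
  const int h = X.nrow(), w = X.ncol(), r = radius;
  const int ph = h + 2 * r, pw = w + 2 * r;
  // summed-area table over the replicate-padded image
  std::vector<double> S((ph + 1) * (pw + 1), 0.0);
  for (int i = 0; i < ph; ++i) {
    double rowsum = 0.0;
    for (int j = 0; j < pw; ++j) {
      rowsum += X(clampi(i - r, h), clampi(j - r, w));
      S[(i + 1) * (pw + 1) + (j + 1)] = S[i * (pw + 1) + (j + 1)] + rowsum;
    }
  }
  const double area = (double)(2 * r + 1) * (2 * r + 1);
  NumericMatrix O(h, w);
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < w; ++j) {
      // window in padded coords: rows i..i+2r, cols j..j+2r
      double s = S[(i + 2 * r + 1) * (pw + 1) + (j + 2 * r + 1)]
               - S[i * (pw + 1) + (j + 2 * r + 1)]
               - S[(i + 2 * r + 1) * (pw + 1) + j]
               + S[i * (pw + 1) + j];
      double v = s / area;
      O(i, j) = round_int ? half_up(v) : v;
    }
  return O;
}

// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix X, int radius) {
  const int h = X.nrow(), w = X.ncol(), r = radius;
  const int win = (2 * r + 1) * (2 * r + 1);
  NumericMatrix O(h, w);
  std::vector<double> buf(win);
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < w; ++j) {
      int k = 0;
      for (int di = -r; di <= r; ++di) {
        int ii = clampi(i + di, h);
        for (int dj = -r; dj <= r; ++dj) buf[k++] = X(ii, clampi(j + dj, w));
      }
      std::nth_element(buf.begin(), buf.begin() + win / 2, buf.end());
      O(i, j) = buf[win / 2];  // odd window: exact middle element
    }
  return O;
}

// Bilateral filter, Tomasi-Manduca weights, window truncated at ceil(3*sigma_d).
// Intensities are expected integer-valued (8-bit after rescale) so the range
// kernel is an exact lookup table over absolute differences.
// [[Rcpp::export]]
NumericMatrix cpp_bilateral_filter(NumericMatrix X, double sigma_d, double sigma_r,
                                   bool round_int) {
  const int h = X.nrow(), w = X.ncol();
  const int r = (int)std::ceil(3.0 * sigma_d);
  const int side = 2 * r + 1;
  std::vector<double> gs(side * side);
  for (int di = -r; di <= r; ++di)
    for (int dj = -r; dj <= r; ++dj)
      gs[(di + r) * side + (dj + r)] =
        std::exp(-((double)di * di + (double)dj * dj) / (2.0 * sigma_d * sigma_d));
  // range LUT over integer absolute differences
  double vmax = 0.0;
  bool integral = true;
  for (int i = 0; i < h * w; ++i) {
    double v = X[i];
    if (v != std::floor(v)) integral = false;
    if (std::fabs(v) > vmax) vmax = std::fabs(v);
  }
  std::vector<double> gr;
  int lut_n = 0;
  if (integral && vmax <= 65535.0) {
    lut_n = (int)vmax + 1;
    gr.resize(lut_n);
    for (int t = 0; t < lut_n; ++t)
      gr[t] = std::exp(-(double)t * t / (2.0 * sigma_r * sigma_r));
  }
  NumericMatrix O(h, w);
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < w; ++j) {
      const double Ip = X(i, j);
      double num = 0.0, den = 0.0;
      for (int di = -r; di <= r; ++di) {
        int ii = clampi(i + di, h);
        for (int dj = -r; dj <= r; ++dj) {
          double Iq = X(ii, clampi(j + dj, w));
          double wgt = gs[(di + r) * side + (dj + r)];
          if (lut_n) wgt *= gr[(int)std::fabs(Ip - Iq)];
          else wgt *= std::exp(-(Ip - Iq) * (Ip - Iq) / (2.0 * sigma_r * sigma_r));
          num += wgt * Iq;
          den += wgt;
        }
      }
      double v = num / den;
      O(i, j) = round_int ? half_up(v) : v;
    }
  return O;
}

// Separable Gaussian blur, kernel truncated at ceil(3*sigma), edge replication.
// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(NumericMatrix X, double sigma, bool round_int) {
  const int h = X.nrow(), w = X.ncol();
  if (sigma <= 0) return clone(X);
  const int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double ks = 0.0;
  for (int d = -r; d <= r; ++d) {
    k[d + r] = std::exp(-(double)d * d / (2.0 * sigma * sigma));
    ks += k[d + r];
  }
  for (int d = 0; d <= 2 * r; ++d) k[d] /= ks;
  NumericMatrix T(h, w), O(h, w);
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < w; ++j) {
      double s = 0.0;
      for (int d = -r; d <= r; ++d) s += k[d + r] * X(i, clampi(j + d, w));
      T(i, j) = s;
    }
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < w; ++j) {
      double s = 0.0;
      for (int d = -r; d <= r; ++d) s += k[d + r] * T(clampi(i + d, h), j);
      O(i, j) = round_int ? half_up(s) : s;
    }
  return O;
}

// Grayscale opening by a spherical-cap structuring element:
// b(dx,dy) = sqrt(radius^2 - dx^2 - dy^2) over the disc dx^2+dy^2 <= radius^2.
// Exact erosion-then-dilation; edge replication.
// [[Rcpp::export]]
NumericMatrix cpp_ball_opening(NumericMatrix X, double radius) {
  const int h = X.nrow(), w = X.ncol();
  const int r = (int)std::floor(radius);
  const int ph = h + 2 * r, pw = w + 2 * r;
  std::vector<int> halfw(2 * r + 1);
  std::vector<std::vector<float>> prof(2 * r + 1);
  for (int dy = -r; dy <= r; ++dy) {
    double rem = radius * radius - (double)dy * dy;
    int hw = (int)std::floor(std::sqrt(std::max(0.0, rem)));
    halfw[dy + r] = hw;
    prof[dy + r].resize(2 * hw + 1);
    for (int dx = -hw; dx <= hw; ++dx)
      prof[dy + r][dx + hw] = (float)std::sqrt(std::max(0.0, rem - (double)dx * dx));
  }
  std::vector<float> pad((size_t)ph * pw), ero((size_t)ph * pw);
  for (int i = 0; i < ph; ++i)
    for (int j = 0; j < pw; ++j)
      pad[(size_t)i * pw + j] = (float)X(clampi(i - r, h), clampi(j - r, w));
  for (int i = 0; i < ph; ++i) {
    for (int j = 0; j < pw; ++j) {
      float m = 1e30f;
      for (int dy = -r; dy <= r; ++dy) {
        int ii = clampi(i + dy, ph);
        const float* row = &pad[(size_t)ii * pw];
        const float* b = &prof[dy + r][0];
        const int hw = halfw[dy + r];
        const int j0 = j - hw, j1 = j + hw;
        if (j0 >= 0 && j1 < pw) {
          const float* p = row + j0;
          for (int k = 0; k <= 2 * hw; ++k) {
            float v = p[k] - b[k];
            if (v < m) m = v;
          }
        } else {
          for (int k = 0; k <= 2 * hw; ++k) {
            float v = row[clampi(j0 + k, pw)] - b[k];
            if (v < m) m = v;
          }
        }
      }
      ero[(size_t)i * pw + j] = m;
    }
  }
  NumericMatrix O(h, w);
  for (int i = 0; i < h; ++i) {
    for (int j = 0; j < w; ++j) {
      const int pi = i + r, pj = j + r;
      float m = -1e30f;
      for (int dy = -r; dy <= r; ++dy) {
        const float* row = &ero[(size_t)(pi + dy) * pw];
        const float* b = &prof[dy + r][0];
        const int hw = halfw[dy + r];
        const float* p = row + (pj - hw);
        for (int k = 0; k <= 2 * hw; ++k) {
          float v = p[k] + b[k];
          if (v > m) m = v;
        }
      }
      O(i, j) = m;
    }
  }
  return O;
}

// Block minimum over s x s tiles (image padded by edge replication to a
// multiple of s). Used by the down-sampled rolling-ball background estimate.
// [[Rcpp::export]]
NumericMatrix cpp_block_min(NumericMatrix X, int s) {
  const int h = X.nrow(), w = X.ncol();
  const int oh = (h + s - 1) / s, ow = (w + s - 1) / s;
  NumericMatrix O(oh, ow);
  for (int bi = 0; bi < oh; ++bi)
    for (int bj = 0; bj < ow; ++bj) {
      double m = R_PosInf;
      for (int di = 0; di < s; ++di)
        for (int dj = 0; dj < s; ++dj) {
          double v = X(clampi(bi * s + di, h), clampi(bj * s + dj, w));
          if (v < m) m = v;
        }
      O(bi, bj) = m;
    }
  return O;
}
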