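#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Windowed pixel loops for 8-bit rasters. Images are numeric matrices
// (rows = image rows, cols = image columns). Border rule for the gray
// filters is edge replication; binary morphology treats everything
// outside the raster as background (0).

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// round half up, matching integer accumulation of 8-bit values
static inline double rhu(double x) { return std::floor(x + 0.5); }

// [[Rcpp::export(name = ".mean_filter_cpp")]]
NumericMatrix mean_filter_cpp(NumericMatrix img, int kw, int kh) {
  const int nr = img.nrow(), nc = img.ncol();
  const int a = (kw - 1) / 2, b = (kh - 1) / 2;
  const double area = (double)kw * (double)kh;
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double s = 0.0;
      for (int dr = -b; dr <= b; ++dr) {
        const int rr = clampi(r + dr, 0, nr - 1);
        for (int dc = -a; dc <= a; ++dc) {
          s += img(rr, clampi(c + dc, 0, nc - 1));
        }
      }
      out(r, c) = rhu(s / area);
    }
  }
  return out;
}

// [[Rcpp::export(name = ".median_filter_cpp")]]
NumericMatrix median_filter_cpp(NumericMatrix img, int kw, int kh) {
  const int nr = img.nrow(), nc = img.ncol();
  const int a = (kw - 1) / 2, b = (kh - 1) / 2;
  const int n = kw * kh;
  std::vector<double> win((size_t)n);
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int k = 0;
      for (int dr = -b; dr <= b; ++dr) {
        const int rr = clampi(r + dr, 0, nr - 1);
        for (int dc = -a; dc <= a; ++dc) {
          win[(size_t)k++] = img(rr, clampi(c + dc, 0, nc - 1));
        }
      }
      std::nth_element(win.begin(), win.begin() + n / 2, win.end());
      out(r, c) = win[(size_t)(n / 2)]; // n odd => exact order statistic
    }
  }
  return out;
}

// [[Rcpp::export(name = ".bilateral_filter_cpp")]]
NumericMatrix bilateral_filter_cpp(NumericMatrix img, int radius,
                                   double sigma_spatial, double sigma_range) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  const double inv2ss = 1.0 / (2.0 * sigma_spatial * sigma_spatial);
  const double inv2sr = 1.0 / (2.0 * sigma_range * sigma_range);
  // spatial weights are fixed over the window; precompute
  const int side = 2 * radius + 1;
  std::vector<double> gs((size_t)side * side);
  for (int dr = -radius; dr <= radius; ++dr)
    for (int dc = -radius; dc <= radius; ++dc)
      gs[(size_t)((dr + radius) * side + (dc + radius))] =
        std::exp(-((double)(dr * dr + dc * dc)) * inv2ss);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      const double center = img(r, c);
      double wsum = 0.0, acc = 0.0;
      for (int dr = -radius; dr <= radius; ++dr) {
        const int rr = clampi(r + dr, 0, nr - 1);
        for (int dc = -radius; dc <= radius; ++dc) {
          const double v = img(rr, clampi(c + dc, 0, nc - 1));
          const double d = v - center;
          const double w = gs[(size_t)((dr + radius) * side + (dc + radius))] *
                           std::exp(-d * d * inv2sr);
          wsum += w;
          acc += w * v;
        }
      }
      out(r, c) = rhu(acc / wsum);
    }
  }
  return out;
}

// local block mean with replicated borders (adaptive-threshold statistic);
// left unrounded so the caller compares against the exact mean
// [[Rcpp::export(name = ".box_mean_cpp")]]
NumericMatrix box_mean_cpp(NumericMatrix img, int block) {
  const int nr = img.nrow(), nc = img.ncol();
  const int h = (block - 1) / 2;
  const double area = (double)block * (double)block;
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double s = 0.0;
      for (int dr = -h; dr <= h; ++dr) {
        const int rr = clampi(r + dr, 0, nr - 1);
        for (int dc = -h; dc <= h; ++dc)
          s += img(rr, clampi(c + dc, 0, nc - 1));
      }
      out(r, c) = s / area;
    }
  }
  return out;
}

// Minkowski dilation of the white (255) set; outside the raster is background
// [[Rcpp::export(name = ".dilate_cpp")]]
NumericMatrix dilate_cpp(NumericMatrix img, LogicalMatrix se,
                         int origin_r, int origin_c) {
  const int nr = img.nrow(), nc = img.ncol();
  const int mr = se.nrow(), mc = se.ncol();
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      bool hit = false;
      for (int i = 0; i < mr && !hit; ++i) {
        for (int j = 0; j < mc && !hit; ++j) {
          if (!se(i, j)) continue;
          const int rr = r - (i - origin_r);
          const int cc = c - (j - origin_c);
          if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && img(rr, cc) > 0)
            hit = true;
        }
      }
      out(r, c) = hit ? 255.0 : 0.0;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".erode_cpp")]]
NumericMatrix erode_cpp(NumericMatrix img, LogicalMatrix se,
                        int origin_r, int origin_c) {
  const int nr = img.nrow(), nc = img.ncol();
  const int mr = se.nrow(), mc = se.ncol();
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      bool all = true;
      for (int i = 0; i < mr && all; ++i) {
        for (int j = 0; j < mc && all; ++j) {
          if (!se(i, j)) continue;
          const int rr = r + (i - origin_r);
          const int cc = c + (j - origin_c);
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc || img(rr, cc) <= 0)
            all = false;
        }
      }
      out(r, c) = all ? 255.0 : 0.0;
    }
  }
  return out;
}

// Canny stages: 3x3 Sobel gradient (replicated borders), direction-quantized
// non-maximum suppression, then double-threshold hysteresis (8-connected).
// NMS keeps a pixel when its magnitude strictly exceeds the neighbor in the
// positive gradient direction and is >= the neighbor in the negative
// direction, so a two-pixel step plateau thins to a single-pixel line.
// [[Rcpp::export(name = ".canny_cpp")]]
NumericMatrix canny_cpp(NumericMatrix img, double low, double high) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix mag(nr, nc);
  IntegerMatrix dir(nr, nc); // 0: E-W, 1: NE-SW, 2: N-S, 3: NW-SE
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      const int rm = clampi(r - 1, 0, nr - 1), rp = clampi(r + 1, 0, nr - 1);
      const int cm = clampi(c - 1, 0, nc - 1), cp = clampi(c + 1, 0, nc - 1);
      const double gx = (img(rm, cp) + 2.0 * img(r, cp) + img(rp, cp)) -
                        (img(rm, cm) + 2.0 * img(r, cm) + img(rp, cm));
      const double gy = (img(rp, cm) + 2.0 * img(rp, c) + img(rp, cp)) -
                        (img(rm, cm) + 2.0 * img(rm, c) + img(rm, cp));
      mag(r, c) = std::sqrt(gx * gx + gy * gy);
      double ang = std::atan2(gy, gx) * 180.0 / M_PI;
      if (ang < 0) ang += 180.0;
      int d;
      if (ang < 22.5 || ang >= 157.5) d = 0;
      else if (ang < 67.5) d = 1;
      else if (ang < 112.5) d = 2;
      else d = 3;
      dir(r, c) = d;
    }
  }
  // offsets (dr, dc) for the positive direction of each quantized angle
  const int off[4][2] = { {0, 1}, {1, 1}, {1, 0}, {1, -1} };
  IntegerMatrix keep(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      const double m = mag(r, c);
      if (m < low) { keep(r, c) = 0; continue; }
      const int d = dir(r, c);
      const int r1 = r + off[d][0], c1 = c + off[d][1];
      const int r2 = r - off[d][0], c2 = c - off[d][1];
      const double m1 = (r1 >= 0 && r1 < nr && c1 >= 0 && c1 < nc) ? mag(r1, c1) : 0.0;
      const double m2 = (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc) ? mag(r2, c2) : 0.0;
      keep(r, c) = (m > m1 && m >= m2) ? 1 : 0;
    }
  }
  // hysteresis: seed from strong candidates, grow through weak ones
  NumericMatrix out(nr, nc);
  std::queue<std::pair<int, int> > q;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if (keep(r, c) && mag(r, c) >= high) {
        out(r, c) = 255.0;
        q.push(std::make_pair(r, c));
      }
  while (!q.empty()) {
    const std::pair<int, int> p = q.front();
    q.pop();
    for (int dr = -1; dr <= 1; ++dr) {
      for (int dc = -1; dc <= 1; ++dc) {
        const int rr = p.first + dr, cc = p.second + dc;
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (out(rr, cc) == 0.0 && keep(rr, cc) && mag(rr, cc) >= low) {
          out(rr, cc) = 255.0;
          q.push(std::make_pair(rr, cc));
        }
      }
    }
  }
  return out;
}

// Sobel gradient magnitude alone (exposed for diagnostics and tests)
// [[Rcpp::export(name = ".sobel_mag_cpp")]]
NumericMatrix sobel_mag_cpp(NumericMatrix img) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix mag(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      const int rm = clampi(r - 1, 0, nr - 1), rp = clampi(r + 1, 0, nr - 1);
      const int cm = clampi(c - 1, 0, nc - 1), cp = clampi(c + 1, 0, nc - 1);
      const double gx = (img(rm, cp) + 2.0 * img(r, cp) + img(rp, cp)) -
                        (img(rm, cm) + 2.0 * img(r, cm) + img(rp, cm));
      const double gy = (img(rp, cm) + 2.0 * img(rp, c) + img(rp, cp)) -
                        (img(rm, cm) + 2.0 * img(rm, c) + img(rm, cp));
      mag(r, c) = std::sqrt(gx * gx + gy * gy);
    }
  }
  return mag;
}
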