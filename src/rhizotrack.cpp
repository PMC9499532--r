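#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Zhang-Suen binary thinning. Input/output: 0/1 integer matrix.
// Preserves 8-connectivity and line endpoints; deterministic.
// [[Rcpp::export(name = ".cpp_thin")]]
IntegerMatrix cpp_thin(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix img(clone(mask));
  std::vector<int> kill;
  kill.reserve(1024);
  bool changed = true;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      kill.clear();
      for (int j = 1; j < nc - 1; ++j) {
        for (int i = 1; i < nr - 1; ++i) {
          if (!img(i, j)) continue;
          // neighbours P2..P9 clockwise starting north
          int p2 = img(i - 1, j),     p3 = img(i - 1, j + 1);
          int p4 = img(i, j + 1),     p5 = img(i + 1, j + 1);
          int p6 = img(i + 1, j),     p7 = img(i + 1, j - 1);
          int p8 = img(i, j - 1),     p9 = img(i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (sub == 0) {
            if (p2 * p4 * p6 != 0) continue;
            if (p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0) continue;
            if (p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(i + j * nr);
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t k = 0; k < kill.size(); ++k) img[kill[k]] = 0;
      }
    }
  }
  return img;
}

// 3x3 median filter ("Despeckle"); edges replicated.
// [[Rcpp::export(name = ".cpp_median3")]]
NumericMatrix cpp_median3(NumericMatrix x) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  double v[9];
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int k = 0;
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = j + dj;
        if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
        for (int di = -1; di <= 1; ++di) {
          int ii = i + di;
          if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
          v[k++] = x(ii, jj);
        }
      }
      // median of 9 by partial selection
      std::nth_element(v, v + 4, v + 9);
      out(i, j) = v[4];
    }
  }
  return out;
}

static inline void stamp_disc(NumericMatrix &out, int ci, int cj,
                              int radius, double value, bool erase,
                              bool clip, double px0, double py0,
                              double ux, double uy, double len) {
  int nr = out.nrow(), nc = out.ncol();
  int r2 = radius * radius;
  for (int dj = -radius; dj <= radius; ++dj) {
    for (int di = -radius; di <= radius; ++di) {
      if (di * di + dj * dj > r2) continue;
      int i = ci + di, j = cj + dj;
      if (i < 0 || j < 0 || i >= nr || j >= nc) continue;
      if (clip) {
        // butt cap: keep only pixels whose projection on the segment axis
        // lies within the segment (no overshoot past the endpoints)
        double t = (j - px0) * ux + (i - py0) * uy;
        if (t < -0.5 || t > len + 0.5) continue;
      }
      if (erase) out(i, j) = 0.0;
      else if (value > out(i, j)) out(i, j) = value;
    }
  }
}

// Rasterize thick line segments into `out` (modified in place, returned).
// segs columns: x0, y0, x1, y1, value -- 0-based pixel coordinates,
// x = column, y = row. Pixel value := max(old, value); erase=true zeroes.
// butt_cap=true clips the stamped discs to the segment's axial extent.
// [[Rcpp::export(name = ".cpp_draw_segments")]]
NumericMatrix cpp_draw_segments(NumericMatrix out, NumericMatrix segs,
                                int radius, bool erase,
                                bool butt_cap = false) {
  int n = segs.nrow();
  for (int s = 0; s < n; ++s) {
    int x0 = (int)std::lround(segs(s, 0)), y0 = (int)std::lround(segs(s, 1));
    int x1 = (int)std::lround(segs(s, 2)), y1 = (int)std::lround(segs(s, 3));
    double v = segs(s, 4);
    double len = std::sqrt((double)(x1 - x0) * (x1 - x0) +
                           (double)(y1 - y0) * (y1 - y0));
    double ux = len > 0 ? (x1 - x0) / len : 1.0;
    double uy = len > 0 ? (y1 - y0) / len : 0.0;
    int dx = std::abs(x1 - x0), dy = std::abs(y1 - y0);
    int sx = x0 < x1 ? 1 : -1, sy = y0 < y1 ? 1 : -1;
    int err = dx - dy;
    int x = x0, y = y0;
    while (true) {
      stamp_disc(out, y, x, radius, v, erase, butt_cap,
                 (double)x0, (double)y0, ux, uy, len);
      if (x == x1 && y == y1) break;
      int e2 = 2 * err;
      if (e2 > -dy) { err -= dy; x += sx; }
      if (e2 < dx)  { err += dx; y += sy; }
    }
  }
  return out;
}

// Translation-only registration by normalized cross-correlation.
// template region: rows [ti0, ti0+th), cols [tj0, tj0+tw) of `ref` (0-based).
// Searches integer shifts (di, dj) in [-max_shift, max_shift]; returns the
// shift of `frame` relative to `ref` maximising NCC, plus the peak value.
// [[Rcpp::export(name = ".cpp_ncc_shift")]]
List cpp_ncc_shift(NumericMatrix ref, NumericMatrix frame,
                   int ti0, int tj0, int th, int tw, int max_shift) {
  int nr = ref.nrow(), nc = ref.ncol();
  double tmean = 0.0;
  for (int j = 0; j < tw; ++j)
    for (int i = 0; i < th; ++i) tmean += ref(ti0 + i, tj0 + j);
  int npix = th * tw;
  tmean /= npix;
  double tss = 0.0;
  for (int j = 0; j < tw; ++j)
    for (int i = 0; i < th; ++i) {
      double d = ref(ti0 + i, tj0 + j) - tmean;
      tss += d * d;
    }
  double best = R_NegInf;
  int bdi = 0, bdj = 0;
  for (int dj = -max_shift; dj <= max_shift; ++dj) {
    for (int di = -max_shift; di <= max_shift; ++di) {
      int fi0 = ti0 + di, fj0 = tj0 + dj;
      if (fi0 < 0 || fj0 < 0 || fi0 + th > nr || fj0 + tw > nc) continue;
      double fmean = 0.0;
      for (int j = 0; j < tw; ++j)
        for (int i = 0; i < th; ++i) fmean += frame(fi0 + i, fj0 + j);
      fmean /= npix;
      double num = 0.0, fss = 0.0;
      for (int j = 0; j < tw; ++j)
        for (int i = 0; i < th; ++i) {
          double ft = frame(fi0 + i, fj0 + j) - fmean;
          double rt = ref(ti0 + i, tj0 + j) - tmean;
          num += ft * rt;
          fss += ft * ft;
        }
      double den = std::sqrt(tss * fss);
      double ncc = den > 0 ? num / den : 0.0;
      if (ncc > best) { best = ncc; bdi = di; bdj = dj; }
    }
  }
  return List::create(_["di"] = bdi, _["dj"] = bdj, _["corr"] = best);
}
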