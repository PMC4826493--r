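#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Symmetric (half-sample) reflection: index -1 maps to 0, n maps to n-1.
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n;
  i = ((i % period) + period) % period;
  if (i >= n) i = period - 1 - i;
  return i;
}

//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_sd_filter(NumericMatrix x, int radius) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  int w = 2 * radius + 1;
  double n = (double)(w * w);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      double s = 0.0, s2 = 0.0;
      for (int di = -radius; di <= radius; ++di) {
        int ii = reflect_idx(i + di, nr);
        for (int dj = -radius; dj <= radius; ++dj) {
          int jj = reflect_idx(j + dj, nc);
          double v = x(ii, jj);
          s += v;
          s2 += v * v;
        }
      }
      double var = s2 / n - (s / n) * (s / n);
      out(i, j) = var > 0.0 ? std::sqrt(var) : 0.0;
    }
  }
  return out;
}

// Binary dilation with a Euclidean disc of (possibly fractional) pixel
// radius.  Stamps the structuring element over every foreground pixel.
//' @noRd
// [[Rcpp::export]]
LogicalMatrix cpp_dilate_disc(LogicalMatrix mask, double radius_px) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out(nr, nc);
  int r = (int)std::floor(radius_px);
  double r2 = radius_px * radius_px;
  std::vector<int> od, oc;
  for (int di = -r; di <= r; ++di)
    for (int dj = -r; dj <= r; ++dj)
      if ((double)(di * di + dj * dj) <= r2) { od.push_back(di); oc.push_back(dj); }
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j)) continue;
      for (size_t k = 0; k < od.size(); ++k) {
        int ii = i + od[k], jj = j + oc[k];
        if (ii >= 0 && ii < nr && jj >= 0 && jj < nc) out(ii, jj) = true;
      }
    }
  return out;
}

// 8-connected component labelling by iterative flood fill.
//' @noRd
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int j0 = 0; j0 < nc; ++j0) {
    for (int i0 = 0; i0 < nr; ++i0) {
      if (!mask(i0, j0) || lab(i0, j0) != 0) continue;
      ++next;
      stack.push_back(i0 + j0 * nr);
      lab(i0, j0) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int i = p % nr, j = p / nr;
        for (int di = -1; di <= 1; ++di)
          for (int dj = -1; dj <= 1; ++dj) {
            int ii = i + di, jj = j + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            if (mask(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              stack.push_back(ii + jj * nr);
            }
          }
      }
    }
  }
  return lab;
}

// Even-odd point-in-polygon test; boundary behaviour is half-open and
// adequate for rasterisation at sub-pixel offsets.
//' @noRd
// [[Rcpp::export]]
LogicalVector cpp_points_in_poly(NumericVector px, NumericVector py,
                                 NumericVector vx, NumericVector vy) {
  int np = px.size(), nv = vx.size();
  LogicalVector out(np);
  for (int k = 0; k < np; ++k) {
    double x = px[k], y = py[k];
    bool inside = false;
    for (int i = 0, j = nv - 1; i < nv; j = i++) {
      if (((vy[i] > y) != (vy[j] > y)) &&
          (x < (vx[j] - vx[i]) * (y - vy[i]) / (vy[j] - vy[i]) + vx[i]))
        inside = !inside;
    }
    out[k] = inside;
  }
  return out;
}

// Circle-overlap heat map: for every (gy, gx) grid point, the number of
// cells whose centroid lies within `radius` (boundary inclusive).
//' @noRd
// [[Rcpp::export]]
IntegerMatrix cpp_heatmap_counts(NumericVector gx, NumericVector gy,
                                 NumericVector cx, NumericVector cy,
                                 double radius) {
  int nx = gx.size(), ny = gy.size(), nc = cx.size();
  IntegerMatrix out(ny, nx);
  double r2 = radius * radius;
  for (int c = 0; c < nc; ++c) {
    for (int j = 0; j < nx; ++j) {
      double dx = gx[j] - cx[c];
      if (dx * dx > r2) continue;
      for (int i = 0; i < ny; ++i) {
        double dy = gy[i] - cy[c];
        if (dx * dx + dy * dy <= r2) out(i, j) += 1;
      }
    }
  }
  return out;
}
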