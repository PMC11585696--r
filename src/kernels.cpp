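#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// ---- exact squared Euclidean distance transform (Felzenszwalb-Huttenlocher) ----
// 1D lower-envelope transform of f; d[i] = min_j (i-j)^2 + f[j]
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Squared Euclidean distance (in pixels^2) from every pixel to the nearest
// TRUE pixel of `feature`. Exact, center-to-center.
// [[Rcpp::export(name = ".edt_sq")]]
NumericMatrix edt_sq(LogicalMatrix feature) {
  int nr = feature.nrow(), nc = feature.ncol();
  // large finite sentinel: keeps the parabola-intersection arithmetic exact
  // (all quantities stay integer-valued doubles) and can never beat a real
  // squared distance (<= nr^2 + nc^2) when any feature pixel exists
  const double INF = 1e12;
  NumericMatrix out(nr, nc);
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // pass 1: columns
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) f[i] = feature(i, j) ? 0.0 : INF;
    dt1d(f, d, nr);
    for (int i = 0; i < nr; i++) out(i, j) = d[i];
  }
  // pass 2: rows
  for (int i = 0; i < nr; i++) {
    for (int j = 0; j < nc; j++) f[j] = out(i, j);
    dt1d(f, d, nc);
    for (int j = 0; j < nc; j++) out(i, j) = d[j];
  }
  return out;
}

// ---- windowed median over non-excluded pixels ----
// For each pixel where `where` is TRUE, the median of img values in the
// square window of half-width h (pixels) centered there, skipping pixels
// where `exclude` is TRUE. NA when the window holds no usable pixel.
// [[Rcpp::export(name = ".win_median")]]
NumericMatrix win_median(NumericMatrix img, LogicalMatrix where,
                         LogicalMatrix exclude, int h) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<double> buf;
  buf.reserve((2 * h + 1) * (2 * h + 1));
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) {
      if (!where(i, j)) continue;
      buf.clear();
      int i0 = std::max(0, i - h), i1 = std::min(nr - 1, i + h);
      int j0 = std::max(0, j - h), j1 = std::min(nc - 1, j + h);
      for (int jj = j0; jj <= j1; jj++)
        for (int ii = i0; ii <= i1; ii++)
          if (!exclude(ii, jj)) buf.push_back(img(ii, jj));
      int m = (int)buf.size();
      if (m == 0) continue;
      int mid = m / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double med = buf[mid];
      if (m % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + mid);
        med = (med + lo) / 2.0;
      }
      out(i, j) = med;
    }
  }
  return out;
}

// ---- 8-connected component labelling (iterative flood fill) ----
// [[Rcpp::export(name = ".label8")]]
IntegerMatrix label8(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<std::pair<int, int> > stack;
  int next = 0;
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      next++;
      stack.push_back(std::make_pair(i, j));
      lab(i, j) = next;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int dj = -1; dj <= 1; dj++) {
          for (int di = -1; di <= 1; di++) {
            int ii = p.first + di, jj = p.second + dj;
            if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
            if (mask(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              stack.push_back(std::make_pair(ii, jj));
            }
          }
        }
      }
    }
  }
  return lab;
}

static double rank_cor(const std::vector<double>& rx, const std::vector<double>& ry) {
  int n = (int)rx.size();
  double mx = 0, my = 0;
  for (int i = 0; i < n; i++) { mx += rx[i]; my += ry[i]; }
  mx /= n; my /= n;
  double sxy = 0, sxx = 0, syy = 0;
  for (int i = 0; i < n; i++) {
    double a = rx[i] - mx, b = ry[i] - my;
    sxy += a * b; sxx += a * a; syy += b * b;
  }
  if (sxx <= 0 || syy <= 0) return NA_REAL;
  return sxy / std::sqrt(sxx * syy);
}

// Exact permutation two-sided p for Spearman's rho on average ranks.
// rx, ry are the (average) rank vectors; every distinct arrangement of ry is
// enumerated once via next_permutation, which with ties weights arrangements
// uniformly because each has identical multiplicity.
// [[Rcpp::export(name = ".spearman_perm_p")]]
double spearman_perm_p(NumericVector rx, NumericVector ry) {
  int n = rx.size();
  std::vector<double> vx(rx.begin(), rx.end());
  std::vector<double> vy(ry.begin(), ry.end());
  double obs = std::fabs(rank_cor(vx, vy));
  std::sort(vy.begin(), vy.end());
  long long hits = 0, total = 0;
  do {
    double r = rank_cor(vx, vy);
    if (std::fabs(r) >= obs - 1e-12) hits++;
    total++;
  } while (std::next_permutation(vy.begin(), vy.end()));
  return (double)hits / (double)total;
}
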