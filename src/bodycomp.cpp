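#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Bilinear sample of column-major `p` at continuous 0-based (r, c); caller
// guarantees 0 <= r <= nr-1 and 0 <= c <= nc-1.
static inline double bilin(const double *p, int nr, int nc, double r, double c) {
  int i0 = (int)std::floor(r); if (i0 > nr - 2) i0 = nr - 2;
  int j0 = (int)std::floor(c); if (j0 > nc - 2) j0 = nc - 2;
  double fr = r - i0, fc = c - j0;
  const double *base = p + (size_t)j0 * nr + i0;
  return (1.0 - fr) * (1.0 - fc) * base[0] +
         fr * (1.0 - fc) * base[1] +
         (1.0 - fr) * fc * base[nr] +
         fr * fc * base[nr + 1];
}

static inline double nearest(const double *p, int nr, int nc, double r, double c) {
  int i = (int)std::floor(r + 0.5); if (i < 0) i = 0; if (i > nr - 1) i = nr - 1;
  int j = (int)std::floor(c + 0.5); if (j < 0) j = 0; if (j > nc - 1) j = nc - 1;
  return p[(size_t)j * nr + i];
}

// Accumulate probabilities along one ray. Samples at k = 1, 2, ... physical
// steps of step_mm; stops at the first sample outside the grid. Origin pixel
// is excluded by construction.
// [[Rcpp::export]]
double cpp_accumulate_ray(NumericMatrix prob, double oi, double oj,
                          double ur, double uc, double step_mm,
                          double row_mm, double col_mm, int interp) {
  int nr = prob.nrow(), nc = prob.ncol();
  const double *p = prob.begin();
  double di = step_mm * ur / row_mm;
  double dj = step_mm * uc / col_mm;
  double acc = 0.0;
  for (int k = 1; ; ++k) {
    double r = oi + k * di;
    double c = oj + k * dj;
    if (r < 0.0 || r > nr - 1.0 || c < 0.0 || c > nc - 1.0) break;
    acc += (interp == 0) ? bilin(p, nr, nc, r, c) : nearest(p, nr, nc, r, c);
    if (k > 100000) stop("ray failed to leave the grid");
  }
  return acc;
}

// Unnormalized ILT response: per pixel, accumulate along n_dir equally
// spaced directions (theta_d = 2*pi*d/n_dir, physical direction
// (sin theta, cos theta) in (row, col) mm space) and sum the m smallest
// accumulations. Pixels where compute == 0 are skipped (response 0).
// [[Rcpp::export]]
NumericMatrix cpp_ilt_raw(NumericMatrix prob, int n_dir, int m,
                          double step_mm, double row_mm, double col_mm,
                          int interp, IntegerMatrix compute) {
  int nr = prob.nrow(), nc = prob.ncol();
  const double *p = prob.begin();
  bool use_mask = compute.nrow() == nr && compute.ncol() == nc;
  NumericMatrix out(nr, nc);
  std::vector<double> di(n_dir), dj(n_dir);
  for (int d = 0; d < n_dir; ++d) {
    double th = 2.0 * M_PI * d / n_dir;
    di[d] = step_mm * std::sin(th) / row_mm;
    dj[d] = step_mm * std::cos(th) / col_mm;
  }
  std::vector<double> acc(n_dir);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (use_mask && compute(i, j) == 0) { out(i, j) = 0.0; continue; }
      for (int d = 0; d < n_dir; ++d) {
        double a = 0.0;
        if (interp == 0) {
          for (int k = 1; ; ++k) {
            double r = i + k * di[d];
            double c = j + k * dj[d];
            if (r < 0.0 || r > nr - 1.0 || c < 0.0 || c > nc - 1.0) break;
            a += bilin(p, nr, nc, r, c);
          }
        } else {
          for (int k = 1; ; ++k) {
            double r = i + k * di[d];
            double c = j + k * dj[d];
            if (r < 0.0 || r > nr - 1.0 || c < 0.0 || c > nc - 1.0) break;
            a += nearest(p, nr, nc, r, c);
          }
        }
        acc[d] = a;
      }
      std::sort(acc.begin(), acc.end());
      double s = 0.0;
      for (int d = 0; d < m; ++d) s += acc[d];
      out(i, j) = s;
    }
  }
  return out;
}

// Connected-component labelling of a logical mask, BFS flood fill.
// conn is 4 or 8. Labels are 1..k in scan order, 0 = background.
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int conn) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nn = (conn == 8) ? 8 : 4;
  int next = 0;
  std::queue<int> q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(i + j * nr);
      while (!q.empty()) {
        int idx = q.front(); q.pop();
        int ci = idx % nr, cj = idx / nr;
        for (int d = 0; d < nn; ++d) {
          int ni = ci + dr8[d], nj = cj + dc8[d];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            q.push(ni + nj * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Fill holes: background pixels not reachable from the image border through
// background (with the given connectivity) become foreground.
// [[Rcpp::export]]
LogicalMatrix cpp_fill_holes(LogicalMatrix mask, int conn) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix reach(nr, nc);
  std::fill(reach.begin(), reach.end(), false);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nn = (conn == 8) ? 8 : 4;
  std::queue<int> q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if ((i == 0 || i == nr - 1 || j == 0 || j == nc - 1) &&
          !mask(i, j) && !reach(i, j)) {
        reach(i, j) = true;
        q.push(i + j * nr);
      }
    }
  }
  while (!q.empty()) {
    int idx = q.front(); q.pop();
    int ci = idx % nr, cj = idx / nr;
    for (int d = 0; d < nn; ++d) {
      int ni = ci + dr8[d], nj = cj + dc8[d];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      if (!mask(ni, nj) && !reach(ni, nj)) {
        reach(ni, nj) = true;
        q.push(ni + nj * nr);
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = mask(i, j) || !reach(i, j);
  return out;
}

static const double DT_INF = 1e30;

// 1D squared distance transform (lower envelope of parabolas) on a unit
// grid; anisotropy handled by the caller through scaling.
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Spacing-aware Euclidean distance transform (mm). For foreground pixels,
// distance to the nearest background pixel center; 0 on background.
// Returns Inf everywhere if the mask has no background.
// [[Rcpp::export]]
NumericMatrix cpp_edt(LogicalMatrix mask, double row_mm, double col_mm) {
  int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix g(nr, nc);
  // columns pass (along rows within each column), spacing row_mm
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  double r2 = row_mm * row_mm, c2 = col_mm * col_mm;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = mask(i, j) ? DT_INF : 0.0;
    dt1d(f, d, nr);
    for (int i = 0; i < nr; ++i) g(i, j) = (d[i] >= DT_INF) ? DT_INF : d[i] * r2;
  }
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = (g(i, j) >= DT_INF) ? DT_INF : g(i, j) / c2;
    dt1d(f, d, nc);
    for (int j = 0; j < nc; ++j)
      g(i, j) = (d[j] >= DT_INF / c2) ? R_PosInf : std::sqrt(d[j] * c2);
  }
  return g;
}
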