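#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Grayscale erosion by a (possibly non-flat) structuring element given as
// pixel offsets (dx = column shift, dy = row shift) with heights h.
// Offsets falling outside the image are ignored, i.e. the SE is restricted
// to the image domain at the border.
// [[Rcpp::export]]
NumericMatrix cpp_gray_erode(const NumericMatrix& img,
                             const IntegerVector& dx,
                             const IntegerVector& dy,
                             const NumericVector& h) {
  const int nr = img.nrow(), nc = img.ncol(), k = dx.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double m = R_PosInf;
      for (int s = 0; s < k; ++s) {
        const int ii = i + dy[s], jj = j + dx[s];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        const double v = img(ii, jj) - h[s];
        if (v < m) m = v;
      }
      out(i, j) = m;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gray_dilate(const NumericMatrix& img,
                              const IntegerVector& dx,
                              const IntegerVector& dy,
                              const NumericVector& h) {
  const int nr = img.nrow(), nc = img.ncol(), k = dx.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double m = R_NegInf;
      for (int s = 0; s < k; ++s) {
        // reflected SE for dilation
        const int ii = i - dy[s], jj = j - dx[s];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        const double v = img(ii, jj) + h[s];
        if (v > m) m = v;
      }
      out(i, j) = m;
    }
  }
  return out;
}

// Fill background holes: background (0) components not touching the image
// border, under 4-connectivity of the background, become foreground.
// [[Rcpp::export]]
LogicalMatrix cpp_fill_holes(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix reach(nr, nc); // background reachable from border
  std::queue<std::pair<int, int> > q;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if ((i == 0 || i == nr - 1 || j == 0 || j == nc - 1) &&
          !mask(i, j) && !reach(i, j)) {
        reach(i, j) = true;
        q.push(std::make_pair(i, j));
      }
    }
  }
  const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    std::pair<int, int> p = q.front(); q.pop();
    for (int s = 0; s < 4; ++s) {
      const int ii = p.first + di[s], jj = p.second + dj[s];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      if (!mask(ii, jj) && !reach(ii, jj)) {
        reach(ii, jj) = true;
        q.push(std::make_pair(ii, jj));
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      out(i, j) = mask(i, j) || !reach(i, j);
  return out;
}

// Connected-component labeling (4 or 8 connectivity); labels assigned in
// column-major scan order starting at 1.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int nnb;
  int di[8], dj[8];
  if (connectivity == 4) {
    nnb = 4;
    int a[4] = {-1, 1, 0, 0}, b[4] = {0, 0, -1, 1};
    for (int s = 0; s < 4; ++s) { di[s] = a[s]; dj[s] = b[s]; }
  } else {
    nnb = 8;
    int a[8] = {-1, -1, -1, 0, 0, 1, 1, 1}, b[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
    for (int s = 0; s < 8; ++s) { di[s] = a[s]; dj[s] = b[s]; }
  }
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int s = 0; s < nnb; ++s) {
          const int ii = p.first + di[s], jj = p.second + dj[s];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) && !lab(ii, jj)) {
            lab(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  }
  return lab;
}

// Separable Gaussian blur, kernel truncated at 3 sigma and renormalized at
// the border (no padding artefacts).
// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(const NumericMatrix& img, double sigma) {
  const int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  const int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  for (int s = -r; s <= r; ++s)
    k[s + r] = std::exp(-0.5 * (double)s * (double)s / (sigma * sigma));
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j) { // vertical pass
    for (int i = 0; i < nr; ++i) {
      double acc = 0, w = 0;
      for (int s = -r; s <= r; ++s) {
        const int ii = i + s;
        if (ii < 0 || ii >= nr) continue;
        acc += k[s + r] * img(ii, j);
        w += k[s + r];
      }
      tmp(i, j) = acc / w;
    }
  }
  for (int j = 0; j < nc; ++j) { // horizontal pass
    for (int i = 0; i < nr; ++i) {
      double acc = 0, w = 0;
      for (int s = -r; s <= r; ++s) {
        const int jj = j + s;
        if (jj < 0 || jj >= nc) continue;
        acc += k[s + r] * tmp(i, jj);
        w += k[s + r];
      }
      out(i, j) = acc / w;
    }
  }
  return out;
}

static inline double pt_seg_dist2(double px, double py, double x1, double y1,
                                  double x2, double y2) {
  const double vx = x2 - x1, vy = y2 - y1;
  const double L2 = vx * vx + vy * vy;
  double t = L2 > 0 ? ((px - x1) * vx + (py - y1) * vy) / L2 : 0.0;
  if (t < 0) t = 0; else if (t > 1) t = 1;
  const double dx = px - (x1 + t * vx), dy = py - (y1 + t * vy);
  return dx * dx + dy * dy;
}

// Even-odd (ray casting) point-in-polygon; points on the boundary (within
// eps of an edge) count as inside.
// [[Rcpp::export]]
LogicalVector cpp_points_in_polygon(const NumericVector& px,
                                    const NumericVector& py,
                                    const NumericVector& vx,
                                    const NumericVector& vy,
                                    double eps) {
  const int np = px.size(), nv = vx.size();
  LogicalVector out(np);
  const double eps2 = eps * eps;
  for (int p = 0; p < np; ++p) {
    const double x = px[p], y = py[p];
    bool inside = false, boundary = false;
    for (int a = 0, b = nv - 1; a < nv; b = a++) {
      const double x1 = vx[b], y1 = vy[b], x2 = vx[a], y2 = vy[a];
      if (pt_seg_dist2(x, y, x1, y1, x2, y2) <= eps2) { boundary = true; break; }
      if ((y1 > y) != (y2 > y)) {
        const double xc = x1 + (y - y1) / (y2 - y1) * (x2 - x1);
        if (x < xc) inside = !inside;
      }
    }
    out[p] = boundary || inside;
  }
  return out;
}
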