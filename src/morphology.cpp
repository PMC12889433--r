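#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Non-flat grayscale erosion/dilation with a ball structuring element of the
// given pixel radius: the classical "rolling ball" primitive. The ball's
// height profile is w(d) = r - sqrt(r^2 - d^2); out-of-image offsets are
// skipped (equivalent to an unbounded pad for the running extremum).
struct BallOffset {
  int dy, dx;
  double w;
};

static bool by_weight(const BallOffset& a, const BallOffset& b) {
  return a.w < b.w;
}

static NumericMatrix ball_pass(const NumericMatrix& x, int radius,
                               double height_scale, bool erode) {
  int ny = x.nrow(), nx = x.ncol();
  double r2 = (double)radius * radius;
  std::vector<BallOffset> off;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b) {
      double d2 = (double)a * a + (double)b * b;
      if (d2 <= r2) {
        BallOffset o;
        o.dy = a; o.dx = b;
        o.w = (radius - std::sqrt(r2 - d2)) * height_scale;
        off.push_back(o);
      }
    }
  // scanning offsets in increasing ball depth allows an early exit: once
  // the global extremum can no longer beat the current best, deeper
  // offsets cannot either
  std::sort(off.begin(), off.end(), by_weight);
  int K = off.size();
  const double* p = &x[0];
  double gext = erode ? *std::min_element(p, p + (size_t)ny * nx)
                      : *std::max_element(p, p + (size_t)ny * nx);
  NumericMatrix out(ny, nx);
  for (int j = 0; j < nx; ++j) {
    for (int i = 0; i < ny; ++i) {
      double best = erode ? R_PosInf : R_NegInf;
      for (int k = 0; k < K; ++k) {
        double w = off[k].w;
        if (erode ? (gext + w >= best) : (gext - w <= best)) break;
        int ii = i + off[k].dy, jj = j + off[k].dx;
        if (ii < 0 || ii >= ny || jj < 0 || jj >= nx) continue;
        double v = erode ? p[(size_t)jj * ny + ii] + w
                         : p[(size_t)jj * ny + ii] - w;
        if (erode ? (v < best) : (v > best)) best = v;
      }
      out(i, j) = best;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_ball_opening(NumericMatrix x, int radius,
                               double height_scale) {
  NumericMatrix e = ball_pass(x, radius, height_scale, true);
  return ball_pass(e, radius, height_scale, false);
}

// Disk median filter with reflected edges.
// [[Rcpp::export]]
NumericMatrix cpp_disk_median(NumericMatrix x, int radius) {
  int ny = x.nrow(), nx = x.ncol();
  std::vector<int> dy, dx;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if (a * a + b * b <= radius * radius) { dy.push_back(a); dx.push_back(b); }
  int K = dy.size();
  NumericMatrix out(ny, nx);
  std::vector<double> buf(K);
  for (int j = 0; j < nx; ++j) {
    for (int i = 0; i < ny; ++i) {
      for (int k = 0; k < K; ++k) {
        int ii = i + dy[k], jj = j + dx[k];
        // reflect across the border (edge pixel not repeated)
        if (ii < 0) ii = -ii; else if (ii >= ny) ii = 2 * ny - 2 - ii;
        if (jj < 0) jj = -jj; else if (jj >= nx) jj = 2 * nx - 2 - jj;
        if (ii < 0) ii = 0;
        if (ii >= ny) ii = ny - 1;
        if (jj < 0) jj = 0;
        if (jj >= nx) jj = nx - 1;
        buf[k] = x(ii, jj);
      }
      std::nth_element(buf.begin(), buf.begin() + K / 2, buf.end());
      double med = buf[K / 2];
      if (K % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + K / 2 - 1,
                         buf.begin() + K / 2);
        med = (med + buf[K / 2 - 1]) / 2.0;
      }
      out(i, j) = med;
    }
  }
  return out;
}

// Connected-component labeling (breadth-first), 4- or 8-connectivity.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  int ny = mask.nrow(), nx = mask.ncol();
  IntegerMatrix lab(ny, nx);
  int n8y[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  int n8x[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  int n4y[4] = {-1, 0, 0, 1};
  int n4x[4] = {0, -1, 1, 0};
  int *offy = connectivity == 8 ? n8y : n4y;
  int *offx = connectivity == 8 ? n8x : n4x;
  int K = connectivity == 8 ? 8 : 4;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nx; ++j) {
    for (int i = 0; i < ny; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int k = 0; k < K; ++k) {
          int ii = p.first + offy[k], jj = p.second + offx[k];
          if (ii < 0 || ii >= ny || jj < 0 || jj >= nx) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  }
  return lab;
}
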