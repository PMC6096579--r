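// 3D raster primitives for anisotropic confocal stacks.
// Arrays are R column-major with dim = c(nx, ny, nz); linear index
// p = i + nx*(j + ny*k). Connectivity is 6-face throughout.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const int DI[6] = {-1, 1, 0, 0, 0, 0};
static const int DJ[6] = {0, 0, -1, 1, 0, 0};
static const int DK[6] = {0, 0, 0, 0, -1, 1};

// [[Rcpp::export]]
IntegerVector cpp_label_cc(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int p = 0; p < n; ++p) {
    if (!mask[p] || lab[p]) continue;
    ++next;
    lab[p] = next;
    stack.push_back(p);
    while (!stack.empty()) {
      const int q = stack.back(); stack.pop_back();
      const int i = q % nx, j = (q / nx) % ny, k = q / (nx * ny);
      for (int t = 0; t < 6; ++t) {
        const int ii = i + DI[t], jj = j + DJ[t], kk = k + DK[t];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        const int r = ii + nx * (jj + ny * kk);
        if (mask[r] && !lab[r]) { lab[r] = next; stack.push_back(r); }
      }
    }
  }
  return lab;
}

// Lower-envelope 1D squared distance transform (Felzenszwalb-Huttenlocher)
// on samples spaced s apart; f may contain +Inf.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double s) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double sq;
    while (true) {
      const int p = v[k];
      const double xq = q * s, xp = p * s;
      const bool iq = !std::isfinite(f[q]), ip = !std::isfinite(f[p]);
      if (iq && ip)      sq = (xq + xp) / 2.0;
      else if (iq)       sq = INF;
      else if (ip)       sq = -INF;
      else sq = ((f[q] + xq * xq) - (f[p] + xp * xp)) / (2.0 * (xq - xp));
      if (sq <= z[k]) { --k; if (k < 0) break; } else break;
    }
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
    } else {
      ++k; v[k] = q; z[k] = sq; z[k + 1] = INF;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = q * s;
    while (z[k + 1] < xq) ++k;
    const double dx = xq - v[k] * s;
    d[q] = dx * dx + f[v[k]];
  }
}

// Squared Euclidean distance from each foreground voxel to the nearest
// background voxel, in physical units (anisotropic spacing). Background
// voxels get 0. Out-of-grid space is not treated as background.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector fg, IntegerVector dims,
                         NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector d(n);
  for (int p = 0; p < n; ++p) d[p] = fg[p] ? INF : 0.0;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), g(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x lines
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const int base = nx * (j + ny * k);
      for (int i = 0; i < nx; ++i) f[i] = d[base + i];
      dt1d(f, g, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) d[base + i] = g[i];
    }
  // y lines
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      const int base = i + nx * ny * k;
      for (int j = 0; j < ny; ++j) f[j] = d[base + nx * j];
      dt1d(f, g, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) d[base + nx * j] = g[j];
    }
  // z lines
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      const int base = i + nx * j;
      for (int k = 0; k < nz; ++k) f[k] = d[base + nx * ny * k];
      dt1d(f, g, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) d[base + nx * ny * k] = g[k];
    }
  return d;
}

// Grayscale erosion (dilate = false) or dilation (dilate = true) with an
// arbitrary structuring element given as voxel offsets (m x 3). Voxels
// whose offset falls outside the grid are ignored, so flat regions are
// preserved at borders.
// [[Rcpp::export]]
NumericVector cpp_morph_gray(NumericVector img, IntegerVector dims,
                             IntegerMatrix offsets, bool dilate) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz, m = offsets.nrow();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    const int i = p % nx, j = (p / nx) % ny, k = p / (nx * ny);
    double acc = dilate ? -std::numeric_limits<double>::infinity()
                        :  std::numeric_limits<double>::infinity();
    for (int t = 0; t < m; ++t) {
      const int ii = i + offsets(t, 0), jj = j + offsets(t, 1),
                kk = k + offsets(t, 2);
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
        continue;
      const double val = img[ii + nx * (jj + ny * kk)];
      if (dilate) { if (val > acc) acc = val; }
      else        { if (val < acc) acc = val; }
    }
    out[p] = acc;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_median_filter(NumericVector img, IntegerVector dims,
                                IntegerMatrix offsets) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz, m = offsets.nrow();
  NumericVector out(n);
  std::vector<double> buf;
  buf.reserve(m);
  for (int p = 0; p < n; ++p) {
    const int i = p % nx, j = (p / nx) % ny, k = p / (nx * ny);
    buf.clear();
    for (int t = 0; t < m; ++t) {
      const int ii = i + offsets(t, 0), jj = j + offsets(t, 1),
                kk = k + offsets(t, 2);
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
        continue;
      buf.push_back(img[ii + nx * (jj + ny * kk)]);
    }
    const size_t h = buf.size() / 2;
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double med = buf[h];
    if (buf.size() % 2 == 0) {
      std::nth_element(buf.begin(), buf.begin() + h - 1, buf.begin() + h);
      med = (med + buf[h - 1]) / 2.0;
    }
    out[p] = med;
  }
  return out;
}

// Separable 1D convolution along one axis (0 = x, 1 = y, 2 = z) with an
// odd-length kernel; truncated border weights are renormalized.
// [[Rcpp::export]]
NumericVector cpp_convolve_axis(NumericVector img, IntegerVector dims,
                                NumericVector kernel, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  const int klen = kernel.size(), half = klen / 2;
  const int len = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  const int stride = (axis == 0) ? 1 : (axis == 1) ? nx : nx * ny;
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    const int i = p % nx, j = (p / nx) % ny, k = p / (nx * ny);
    const int pos = (axis == 0) ? i : (axis == 1) ? j : k;
    double acc = 0.0, wsum = 0.0;
    for (int t = -half; t <= half; ++t) {
      const int q = pos + t;
      if (q < 0 || q >= len) continue;
      const double w = kernel[t + half];
      acc += w * img[p + t * stride];
      wsum += w;
    }
    out[p] = acc / wsum;
  }
  return out;
}

// Morphological reconstruction by dilation of marker under ceiling
// (requires marker <= ceiling everywhere); Vincent's hybrid algorithm.
// [[Rcpp::export]]
NumericVector cpp_reconstruct_dil(NumericVector marker, NumericVector ceiling,
                                  IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  const int sx = 1, sy = nx, sz = nx * ny;
  NumericVector J = clone(marker);

  // forward raster: causal neighbors
  for (int p = 0; p < n; ++p) {
    const int i = p % nx, j = (p / nx) % ny, k = p / (nx * ny);
    double m = J[p];
    if (i > 0 && J[p - sx] > m) m = J[p - sx];
    if (j > 0 && J[p - sy] > m) m = J[p - sy];
    if (k > 0 && J[p - sz] > m) m = J[p - sz];
    J[p] = std::min(m, (double)ceiling[p]);
  }
  // backward raster + queue seeding
  std::queue<int> fifo;
  for (int p = n - 1; p >= 0; --p) {
    const int i = p % nx, j = (p / nx) % ny, k = p / (nx * ny);
    double m = J[p];
    if (i < nx - 1 && J[p + sx] > m) m = J[p + sx];
    if (j < ny - 1 && J[p + sy] > m) m = J[p + sy];
    if (k < nz - 1 && J[p + sz] > m) m = J[p + sz];
    J[p] = std::min(m, (double)ceiling[p]);
    bool push = false;
    if (i < nx - 1 && J[p + sx] < J[p] && J[p + sx] < ceiling[p + sx]) push = true;
    if (!push && j < ny - 1 && J[p + sy] < J[p] && J[p + sy] < ceiling[p + sy]) push = true;
    if (!push && k < nz - 1 && J[p + sz] < J[p] && J[p + sz] < ceiling[p + sz]) push = true;
    if (push) fifo.push(p);
  }
  while (!fifo.empty()) {
    const int p = fifo.front(); fifo.pop();
    const int i = p % nx, j = (p / nx) % ny, k = p / (nx * ny);
    for (int t = 0; t < 6; ++t) {
      const int ii = i + DI[t], jj = j + DJ[t], kk = k + DK[t];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
        continue;
      const int r = ii + nx * (jj + ny * kk);
      if (J[r] < J[p] && J[r] < ceiling[r]) {
        J[r] = std::min((double)J[p], (double)ceiling[r]);
        fifo.push(r);
      }
    }
  }
  return J;
}

// Seeded watershed by priority flooding within a mask. Seeds carry positive
// labels; unlabeled mask voxels are claimed by the first neighbor popped
// from a min-heap on (priority, linear index), so ties resolve in raster
// order and the result is deterministic.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector priority, IntegerVector seeds,
                            LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  typedef std::pair<double, int> PQE;
  std::priority_queue<PQE, std::vector<PQE>, std::greater<PQE> > pq;
  IntegerVector lab(n, 0);
  for (int p = 0; p < n; ++p)
    if (seeds[p] > 0 && mask[p]) {
      lab[p] = seeds[p];
      pq.push(std::make_pair((double)priority[p], p));
    }
  while (!pq.empty()) {
    const int q = pq.top().second; pq.pop();
    const int i = q % nx, j = (q / nx) % ny, k = q / (nx * ny);
    for (int t = 0; t < 6; ++t) {
      const int ii = i + DI[t], jj = j + DJ[t], kk = k + DK[t];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
        continue;
      const int r = ii + nx * (jj + ny * kk);
      if (mask[r] && lab[r] == 0) {
        lab[r] = lab[q];
        pq.push(std::make_pair((double)priority[r], r));
      }
    }
  }
  return lab;
}
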