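#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 1-D squared distance transform (Felzenszwalb & Huttenlocher), grid step s.
static void dt1d(const double *f, double *d, int n, double s) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  const double s2 = s * s;
  for (int q = 1; q < n; ++q) {
    double sA;
    while (true) {
      int p = v[k];
      sA = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
      if (sA <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = sA;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    d[q] = s2 * (q - p) * (q - p) + f[p];
  }
}

// Euclidean distance (mm) from every voxel to the nearest mask voxel.
// Exact, separable, anisotropic spacing. Distance is 0 inside the mask.
// [[Rcpp::export]]
NumericVector cpp_mask_distance(IntegerVector dims, NumericVector spacing,
                                LogicalVector mask) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask size mismatch");
  // large finite stand-in for "no seed": keeps the parabola intersections
  // finite; far exceeds any realistic squared distance in mm
  const double BIG = 1e15;
  std::vector<double> d((size_t)n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? 0.0 : BIG;

  std::vector<double> buf(std::max(nx, std::max(ny, nz)));
  std::vector<double> out(buf.size());
  // pass along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      bool any = false;
      for (int x = 0; x < nx; ++x) { buf[x] = d[base + x]; if (std::isfinite(buf[x])) any = true; }
      if (!any) continue;
      dt1d(buf.data(), out.data(), nx, spacing[0]);
      for (int x = 0; x < nx; ++x) d[base + x] = out[x];
    }
  // pass along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      bool any = false;
      for (int y = 0; y < ny; ++y) { buf[y] = d[base + (R_xlen_t)y * nx]; if (std::isfinite(buf[y])) any = true; }
      if (!any) continue;
      dt1d(buf.data(), out.data(), ny, spacing[1]);
      for (int y = 0; y < ny; ++y) d[base + (R_xlen_t)y * nx] = out[y];
    }
  // pass along z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      bool any = false;
      for (int z = 0; z < nz; ++z) { buf[z] = d[base + (R_xlen_t)z * nx * ny]; if (std::isfinite(buf[z])) any = true; }
      if (!any) continue;
      dt1d(buf.data(), out.data(), nz, spacing[2]);
      for (int z = 0; z < nz; ++z) d[base + (R_xlen_t)z * nx * ny] = out[z];
    }

  NumericVector res(n);
  for (R_xlen_t i = 0; i < n; ++i)
    res[i] = std::isfinite(d[i]) ? std::sqrt(d[i]) : R_PosInf;
  return res;
}

// Connected-component labelling of a binary mask, 26- or 6-connectivity.
// [[Rcpp::export]]
IntegerVector cpp_components(IntegerVector dims, LogicalVector mask,
                             int connectivity = 26) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n, 0);
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh > 1) continue;
        offs.push_back({dx, dy, dz});
      }
  int cur = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i]) continue;
    labels[i] = ++cur;
    q.push(i);
    while (!q.empty()) {
      R_xlen_t j = q.front(); q.pop();
      int x = (int)(j % nx), y = (int)((j / nx) % ny), z = (int)(j / ((R_xlen_t)nx * ny));
      for (auto &o : offs) {
        int X = x + o[0], Y = y + o[1], Z = z + o[2];
        if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
        R_xlen_t k = (R_xlen_t)Z * nx * ny + (R_xlen_t)Y * nx + X;
        if (mask[k] && !labels[k]) { labels[k] = cur; q.push(k); }
      }
    }
  }
  return labels;
}

// For each row of A (points in mm), the minimum Euclidean distance to any
// row of B. Brute force; surfaces are small.
// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < nb; ++j) {
      double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
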