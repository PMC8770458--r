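#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Squared Euclidean distance transform along one scanline
// (lower-envelope algorithm of Felzenszwalb & Huttenlocher).
// f: squared distances at sample points spaced `step` apart.
static void dt1d(const double *f, double *d, int n, double step,
                 std::vector<int> &v, std::vector<double> &z) {
  if (n == 1) { d[0] = f[0]; return; }
  int k = 0;
  v[0] = 0;
  z[0] = -1e30;
  z[1] = 1e30;
  for (int q = 1; q < n; q++) {
    double xq = q * step;
    double s;
    for (;;) {
      double xv = v[k] * step;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k]) {
        k--;
      } else {
        break;
      }
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double xq = q * step;
    while (z[k + 1] < xq) k++;
    double dx = xq - v[k] * step;
    d[q] = dx * dx + f[v[k]];
  }
}

// Euclidean distance (physical units) from every voxel to the nearest
// TRUE voxel of `mask`. `spacing` gives the voxel size per axis.
// [[Rcpp::export]]
NumericVector cpp_dist_to_set(LogicalVector mask, IntegerVector dims,
                              NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  double *g = REAL(out);
  for (R_xlen_t i = 0; i < n; i++) g[i] = mask[i] ? 0.0 : 1e30;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (fastest-varying index)
  for (int k = 0; k < nz; k++) {
    for (int j = 0; j < ny; j++) {
      double *line = g + (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; i++) f[i] = line[i];
      dt1d(f.data(), d.data(), nx, sx, v, z);
      for (int i = 0; i < nx; i++) line[i] = d[i];
    }
  }
  // pass along y
  for (int k = 0; k < nz; k++) {
    for (int i = 0; i < nx; i++) {
      double *base = g + (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; j++) f[j] = base[(R_xlen_t)j * nx];
      dt1d(f.data(), d.data(), ny, sy, v, z);
      for (int j = 0; j < ny; j++) base[(R_xlen_t)j * nx] = d[j];
    }
  }
  // pass along z
  for (int j = 0; j < ny; j++) {
    for (int i = 0; i < nx; i++) {
      double *base = g + (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; k++) f[k] = base[(R_xlen_t)k * nx * ny];
      dt1d(f.data(), d.data(), nz, sz, v, z);
      for (int k = 0; k < nz; k++) base[(R_xlen_t)k * nx * ny] = d[k];
    }
  }
  for (R_xlen_t i = 0; i < n; i++) g[i] = std::sqrt(g[i]);
  return out;
}

// Connected-component labelling of a 3-D logical mask.
// connectivity: 6 (faces) or 26 (faces + edges + corners).
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out(n);
  int *lab = INTEGER(out);
  for (R_xlen_t i = 0; i < n; i++) lab[i] = 0;

  std::vector<int> offs;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int ad = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && ad != 1) continue;
        offs.push_back(dx);
        offs.push_back(dy);
        offs.push_back(dz);
      }

  std::vector<R_xlen_t> stack;
  int current = 0;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s] != 0) continue;
    current++;
    lab[s] = current;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int pz = (int)(p / ((R_xlen_t)nx * ny));
      R_xlen_t rem = p - (R_xlen_t)pz * nx * ny;
      int py = (int)(rem / nx);
      int px = (int)(rem % nx);
      for (size_t o = 0; o < offs.size(); o += 3) {
        int qx = px + offs[o], qy = py + offs[o + 1], qz = pz + offs[o + 2];
        if (qx < 0 || qx >= nx || qy < 0 || qy >= ny || qz < 0 || qz >= nz)
          continue;
        R_xlen_t q = (R_xlen_t)qz * nx * ny + (R_xlen_t)qy * nx + qx;
        if (mask[q] && lab[q] == 0) {
          lab[q] = current;
          stack.push_back(q);
        }
      }
    }
  }
  return out;
}
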