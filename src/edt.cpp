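#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

// Exact Euclidean distance transform on a 3D voxel grid with per-axis
// spacing, via the separable lower-envelope-of-parabolas algorithm
// (Felzenszwalb & Huttenlocher 2012) applied axis by axis on squared
// distances. Feature voxels are the TRUE entries of the occupancy array;
// the result is the squared Euclidean distance (mm^2) from every voxel
// center to the nearest feature voxel center.

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared-distance transform along a line with sample spacing h.
// f: input squared distances at each sample; d: output.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, double h) {
  const int n = (int)f.size();
  int k = -1;  // index of rightmost parabola in the lower envelope
  for (int q = 0; q < n; q++) {
    if (f[q] == INF) continue;  // no parabola at samples with no feature
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s;
    for (;;) {
      int p = v[k];
      // intersection abscissa (physical units) of parabolas rooted at
      // x = h*p and x = h*q
      s = ((f[q] + h * h * q * q) - (f[p] + h * h * p * p)) /
          (2.0 * h * (q - p));
      if (s <= z[k]) k--; else break;  // z[0] = -INF guards k >= 0
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  if (k < 0) {  // whole line featureless
    for (int q = 0; q < n; q++) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < h * q) k++;
    double dq = h * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_squared")]]
Rcpp::NumericVector edt_squared(Rcpp::LogicalVector occ,
                                Rcpp::IntegerVector dims,
                                Rcpp::NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; i++) g[i] = occ[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // index (i,j,k) -> i + nx*(j + ny*k), column-major like R arrays
  // pass along x
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; i++) f[i] = g[base + i];
      f.resize(nx); d.resize(nx);
      dt1d(f, d, v, z, hx);
      for (int i = 0; i < nx; i++) g[base + i] = d[i];
      f.resize(nmax); d.resize(nmax);
    }
  // pass along y
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      f.resize(ny); d.resize(ny);
      for (int j = 0; j < ny; j++) f[j] = g[base + (R_xlen_t)nx * j];
      dt1d(f, d, v, z, hy);
      for (int j = 0; j < ny; j++) g[base + (R_xlen_t)nx * j] = d[j];
      f.resize(nmax); d.resize(nmax);
    }
  // pass along z
  const R_xlen_t stride = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      f.resize(nz); d.resize(nz);
      for (int k = 0; k < nz; k++) f[k] = g[base + stride * k];
      dt1d(f, d, v, z, hz);
      for (int k = 0; k < nz; k++) g[base + stride * k] = d[k];
      f.resize(nmax); d.resize(nmax);
    }

  Rcpp::NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = g[i];
  return out;
}
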