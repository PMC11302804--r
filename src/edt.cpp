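#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Large-but-finite stand-in for +Inf; keeps the lower-envelope arithmetic
// finite while dominating any realistic squared distance (grids are < 1e3 cm).
static const double DT_LARGE = 1e15;

// 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher 2012),
// with physical sample step so anisotropic voxel spacing is honoured.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, double step) {
  const int n = (int)f.size();
  int k = 0;
  v[0] = 0;
  z[0] = -DT_LARGE;
  z[1] = DT_LARGE;
  for (int q = 1; q < n; ++q) {
    double s = 0.0;
    while (true) {
      const double qq = q * step, vv = v[k] * step;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * qq - 2.0 * vv);
      if (s <= z[k] && k > 0) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_LARGE;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double qq = q * step;
    while (z[k + 1] < qq) ++k;
    const double vv = v[k] * step;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
}

//' @noRd
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(LogicalVector feature, IntegerVector dim,
                         NumericVector spacing) {
  if (dim.size() != 3 || spacing.size() != 3)
    stop("dim and spacing must have length 3");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  if ((R_xlen_t)nx * ny * nz != feature.size())
    stop("feature length does not match dim");
  NumericVector out((R_xlen_t)nx * ny * nz);
  // seed: 0 on feature voxels, "infinity" elsewhere
  for (R_xlen_t i = 0; i < feature.size(); ++i)
    out[i] = feature[i] ? 0.0 : DT_LARGE;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (fastest-varying)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      f.resize(nx); d.resize(nx);
      dt1d(f, d, v, z, spacing[0]);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
      f.resize(nmax); d.resize(nmax);
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j)
        f[j] = out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      f.resize(ny); d.resize(ny);
      dt1d(f, d, v, z, spacing[1]);
      for (int j = 0; j < ny; ++j)
        out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = d[j];
      f.resize(nmax); d.resize(nmax);
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k)
        f[k] = out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      f.resize(nz); d.resize(nz);
      dt1d(f, d, v, z, spacing[2]);
      for (int k = 0; k < nz; ++k)
        out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = d[k];
      f.resize(nmax); d.resize(nmax);
    }
  // voxels unreachable from any feature voxel keep a sentinel distance
  for (R_xlen_t i = 0; i < out.size(); ++i)
    if (out[i] >= DT_LARGE / 2) out[i] = R_PosInf;
  return out;
}
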