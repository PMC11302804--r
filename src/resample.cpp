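#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rigid resampling of a masked 2D map onto its own lattice: output pixel
// (i, j) takes the bilinearly interpolated value of the input at the
// inverse-transformed position (rotation in degrees about the map centre,
// translation in pixel units applied after the rotation). A pixel is valid
// only if all four interpolation corners are valid and in bounds; invalid
// output pixels are NaN.
//' @noRd
// [[Rcpp::export(name = ".rigid_resample_cpp")]]
NumericMatrix rigid_resample_cpp(NumericMatrix x, LogicalMatrix valid,
                                 double rot_deg, double ti_px,
                                 double tj_px) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  const double th = rot_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double ci = (nr + 1) / 2.0, cj = (nc + 1) / 2.0;
  for (int j = 0; j < nc; ++j) {
    const double dj0 = (j + 1) - cj - tj_px;
    for (int i = 0; i < nr; ++i) {
      const double di0 = (i + 1) - ci - ti_px;
      const double si = ci + ct * di0 + st * dj0;
      const double sj = cj - st * di0 + ct * dj0;
      double v = R_NaN;
      if (si >= 1.0 && si <= nr && sj >= 1.0 && sj <= nc) {
        int i0 = (int)std::floor(si);
        int j0 = (int)std::floor(sj);
        if (i0 >= nr) i0 = nr - 1;
        if (j0 >= nc) j0 = nc - 1;
        const double fi = si - i0, fj = sj - j0;
        const int i1 = i0, i2 = i0 + 1; // 1-based corners, i2 <= nr
        const int j1 = j0, j2 = j0 + 1;
        if (valid(i1 - 1, j1 - 1) && valid(i2 - 1, j1 - 1) &&
            valid(i1 - 1, j2 - 1) && valid(i2 - 1, j2 - 1)) {
          v = x(i1 - 1, j1 - 1) * (1 - fi) * (1 - fj) +
              x(i2 - 1, j1 - 1) * fi * (1 - fj) +
              x(i1 - 1, j2 - 1) * (1 - fi) * fj +
              x(i2 - 1, j2 - 1) * fi * fj;
        }
      }
      out(i, j) = v;
    }
  }
  return out;
}

// Normalised cross-correlation between a rigidly transformed moving map
// and a fixed map over their common valid region; returns NCC and overlap
// count (falls back to negative RMS difference when either side is flat).
//' @noRd
// [[Rcpp::export(name = ".rigid_ncc_cpp")]]
NumericVector rigid_ncc_cpp(NumericMatrix mov, LogicalMatrix mov_valid,
                            NumericMatrix fix, LogicalMatrix fix_valid,
                            double rot_deg, double ti_px, double tj_px) {
  NumericMatrix res = rigid_resample_cpp(mov, mov_valid, rot_deg, ti_px,
                                         tj_px);
  const int n = res.size();
  double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
  long cnt = 0;
  for (int k = 0; k < n; ++k) {
    const double a = res[k];
    if (ISNAN(a) || !fix_valid[k]) continue;
    const double b = fix[k];
    sa += a; sb += b; saa += a * a; sbb += b * b; sab += a * b;
    ++cnt;
  }
  NumericVector out(2);
  out[1] = (double)cnt;
  if (cnt < 32) {
    out[0] = R_NegInf;
    return out;
  }
  const double va = saa - sa * sa / cnt, vb = sbb - sb * sb / cnt;
  if (va < 1e-18 || vb < 1e-18) {
    double ss = 0;
    for (int k = 0; k < n; ++k) {
      const double a = res[k];
      if (ISNAN(a) || !fix_valid[k]) continue;
      const double d = a - fix[k];
      ss += d * d;
    }
    out[0] = -std::sqrt(ss / cnt);
    return out;
  }
  out[0] = (sab - sa * sb / cnt) / std::sqrt(va * vb);
  return out;
}
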