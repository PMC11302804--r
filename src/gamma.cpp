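#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct Offset {
  int di, dj;
  double dist2; // squared physical distance, cm^2
};

// Gamma index on co-registered 2D maps. The evaluated distribution is given
// pre-upsampled on a fine lattice (factor m) so that coarse reference pixel
// (i, j) sits on fine node (i*m, j*m) (0-based). Search offsets are visited in
// order of increasing distance and the scan stops once the pure distance term
// exceeds the current best gamma^2 (it can only grow from there).
//' @noRd
// [[Rcpp::export(name = ".gamma_index_cpp")]]
NumericMatrix gamma_index_cpp(NumericMatrix ref, LogicalMatrix ref_valid,
                              NumericMatrix eval_fine,
                              LogicalMatrix eval_valid_fine,
                              int m, double fine_spacing,
                              double dta, double dose_tol,
                              double max_radius) {
  const int nr = ref.nrow(), nc = ref.ncol();
  const int fnr = eval_fine.nrow(), fnc = eval_fine.ncol();
  if (ref_valid.nrow() != nr || ref_valid.ncol() != nc)
    stop("reference validity mask shape mismatch");
  if (eval_valid_fine.nrow() != fnr || eval_valid_fine.ncol() != fnc)
    stop("evaluated validity mask shape mismatch");

  const int rmax = (int)std::floor(max_radius / fine_spacing + 1e-9);
  std::vector<Offset> offs;
  offs.reserve((size_t)(2 * rmax + 1) * (2 * rmax + 1));
  const double r2max = max_radius * max_radius + 1e-12;
  for (int di = -rmax; di <= rmax; ++di)
    for (int dj = -rmax; dj <= rmax; ++dj) {
      const double d2 =
          (double)(di * di + dj * dj) * fine_spacing * fine_spacing;
      if (d2 <= r2max) offs.push_back({di, dj, d2});
    }
  std::sort(offs.begin(), offs.end(),
            [](const Offset& a, const Offset& b) { return a.dist2 < b.dist2; });

  const double dta2 = dta * dta, tol2 = dose_tol * dose_tol;
  NumericMatrix g(nr, nc);
  std::fill(g.begin(), g.end(), NA_REAL);

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!ref_valid(i, j)) continue;
      const double dref = ref(i, j);
      const int fi = i * m, fj = j * m;
      double best = R_PosInf;
      bool found = false;
      for (const Offset& o : offs) {
        const double dterm = o.dist2 / dta2;
        if (dterm >= best) break; // sorted: no later offset can improve
        const int ei = fi + o.di, ej = fj + o.dj;
        if (ei < 0 || ei >= fnr || ej < 0 || ej >= fnc) continue;
        if (!eval_valid_fine(ei, ej)) continue;
        const double dd = eval_fine(ei, ej) - dref;
        const double cand = dterm + dd * dd / tol2;
        if (cand < best) {
          best = cand;
          found = true;
        }
      }
      if (found) g(i, j) = std::sqrt(best);
    }
  }
  return g;
}
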