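#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Median filter restricted to a validity mask: each valid pixel is replaced
// by the median of the valid pixels in its (2*half+1)^2 window (the pixel
// itself included); invalid pixels pass through untouched. Windows are
// clipped at the image border.
//' @noRd
// [[Rcpp::export(name = ".median_filter_masked_cpp")]]
NumericMatrix median_filter_masked_cpp(NumericMatrix x, LogicalMatrix valid,
                                       int half) {
  const int nr = x.nrow(), nc = x.ncol();
  if (valid.nrow() != nr || valid.ncol() != nc)
    stop("mask shape mismatch");
  NumericMatrix out = clone(x);
  std::vector<double> buf;
  buf.reserve((size_t)(2 * half + 1) * (2 * half + 1));
  for (int j = 0; j < nc; ++j) {
    const int j0 = std::max(0, j - half), j1 = std::min(nc - 1, j + half);
    for (int i = 0; i < nr; ++i) {
      if (!valid(i, j)) continue;
      const int i0 = std::max(0, i - half), i1 = std::min(nr - 1, i + half);
      buf.clear();
      for (int jj = j0; jj <= j1; ++jj)
        for (int ii = i0; ii <= i1; ++ii)
          if (valid(ii, jj)) buf.push_back(x(ii, jj));
      const size_t n = buf.size();
      const size_t mid = n / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double med = buf[mid];
      if (n % 2 == 0) {
        const double hi = med;
        std::nth_element(buf.begin(), buf.begin() + mid - 1,
                         buf.begin() + mid);
        med = 0.5 * (buf[mid - 1] + hi);
      }
      out(i, j) = med;
    }
  }
  return out;
}

// Keep only the largest 26-connected component of a 3D logical array.
//' @noRd
// [[Rcpp::export(name = ".largest_component_cpp")]]
LogicalVector largest_component_cpp(LogicalVector mask, IntegerVector dim) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  std::vector<int> label(n, 0);
  int next_label = 0;
  R_xlen_t best_size = 0;
  int best_label = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || label[s] != 0) continue;
    ++next_label;
    R_xlen_t size = 0;
    stack.clear();
    stack.push_back(s);
    label[s] = next_label;
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      ++size;
      const int k = (int)(cur / ((R_xlen_t)nx * ny));
      const int rem = (int)(cur % ((R_xlen_t)nx * ny));
      const int j = rem / nx, i = rem % nx;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            const int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 ||
                kk >= nz)
              continue;
            const R_xlen_t q = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (mask[q] && label[q] == 0) {
              label[q] = next_label;
              stack.push_back(q);
            }
          }
    }
    if (size > best_size) {
      best_size = size;
      best_label = next_label;
    }
  }
  LogicalVector out(n);
  for (R_xlen_t s = 0; s < n; ++s) out[s] = (label[s] == best_label && best_label > 0);
  return out;
}
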