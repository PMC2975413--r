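#include <Rcpp.h>
using namespace Rcpp;

// Two-pass chamfer distance transform. Out-of-image pixels count as
// background, so foreground touching the border gets distance = one step.
// Returns raw integer chamfer weights; the R wrapper divides by w_orth.
// [[Rcpp::export]]
NumericMatrix chamfer_dt_cpp(const LogicalMatrix mask, const int w_orth,
                             const int w_diag) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e15;
  NumericMatrix d(nr, nc);

  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      d(i, j) = mask(i, j) ? INF : 0.0;

  // neighbour value with out-of-image treated as background (0)
  auto at = [&](int i, int j) -> double {
    if (i < 0 || i >= nr || j < 0 || j >= nc) return 0.0;
    return d(i, j);
  };

  // forward raster pass: up, left, up-left, up-right
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j)) continue;
      double v = d(i, j);
      v = std::min(v, at(i - 1, j) + w_orth);
      v = std::min(v, at(i, j - 1) + w_orth);
      v = std::min(v, at(i - 1, j - 1) + w_diag);
      v = std::min(v, at(i - 1, j + 1) + w_diag);
      d(i, j) = v;
    }
  }
  // backward pass: down, right, down-right, down-left
  for (int i = nr - 1; i >= 0; --i) {
    for (int j = nc - 1; j >= 0; --j) {
      if (!mask(i, j)) continue;
      double v = d(i, j);
      v = std::min(v, at(i + 1, j) + w_orth);
      v = std::min(v, at(i, j + 1) + w_orth);
      v = std::min(v, at(i + 1, j + 1) + w_diag);
      v = std::min(v, at(i + 1, j - 1) + w_diag);
      d(i, j) = v;
    }
  }
  return d;
}
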