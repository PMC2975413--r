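#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Moore-neighbour (Freeman chain-code) tracing of the outer boundary of each
// label, summing the supplied orthogonal/diagonal step weights. Interior
// holes are ignored. Isolated pixels fall back to the unit-square perimeter 4.
// Directions are indexed clockwise in image coordinates (row grows downward):
// 0:E 1:SE 2:S 3:SW 4:W 5:NW 6:N 7:NE.
static const int TDR[8] = {0, 1, 1, 1, 0, -1, -1, -1};
static const int TDC[8] = {1, 1, 0, -1, -1, -1, 0, 1};

// [[Rcpp::export]]
NumericVector trace_perimeters_cpp(const IntegerMatrix labels, const int nlab,
                                   const double w_orth, const double w_diag) {
  const int nr = labels.nrow(), nc = labels.ncol();
  NumericVector per(nlab);
  std::vector<int> start_i(nlab + 1, -1), start_j(nlab + 1, -1);

  // first pixel of each label in row-major raster order
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      int l = labels(i, j);
      if (l >= 1 && l <= nlab && start_i[l] < 0) {
        start_i[l] = i;
        start_j[l] = j;
      }
    }

  auto fg = [&](int i, int j, int l) -> bool {
    return i >= 0 && i < nr && j >= 0 && j < nc && labels(i, j) == l;
  };

  for (int l = 1; l <= nlab; ++l) {
    int si = start_i[l], sj = start_j[l];
    if (si < 0) {
      per[l - 1] = NA_REAL;
      continue;
    }
    // raster-first pixel: W/N/NW/NE neighbours are background, so the trace
    // enters from the west; scan clockwise starting just after the backtrack.
    int ci = si, cj = sj, sstart = 5;
    int first_d = -1;
    double total = 0.0;
    long long guard = 8LL * nr * nc + 16;
    bool closed = false;
    while (guard-- > 0) {
      int d = -1;
      for (int k = 0; k < 8; ++k) {
        int dd = (sstart + k) % 8;
        if (fg(ci + TDR[dd], cj + TDC[dd], l)) {
          d = dd;
          break;
        }
      }
      if (d < 0) {  // isolated pixel
        total = 4.0;
        closed = true;
        break;
      }
      if (first_d < 0) {
        first_d = d;
      } else if (ci == si && cj == sj && d == first_d) {
        closed = true;  // Jacob's stopping criterion
        break;
      }
      total += (TDR[d] == 0 || TDC[d] == 0) ? w_orth : w_diag;
      ci += TDR[d];
      cj += TDC[d];
      sstart = (d + 5) % 8;  // neighbour after the backtrack pixel
    }
    per[l - 1] = closed ? total : NA_REAL;
  }
  return per;
}
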