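#include <Rcpp.h>
using namespace Rcpp;

// Per-pixel two-closest-cell assignment. Coordinates are 1-based (row, col),
// matching the package convention. Ties are broken towards the center that
// comes first in the input order, so passing centers sorted by cell id gives
// the documented ascending-id tie rule.
// [[Rcpp::export]]
List two_closest_kernel(NumericVector cy, NumericVector cx, int ny, int nx) {
  const int k = cy.size();
  const int n = ny * nx;
  IntegerVector i1(n), i2(n);
  NumericVector d1(n);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      const int p = x * ny + y;  // column-major, as R stores matrices
      double b1 = R_PosInf, b2 = R_PosInf;
      int j1 = -1, j2 = -1;
      for (int j = 0; j < k; ++j) {
        const double dy = (y + 1) - cy[j];
        const double dx = (x + 1) - cx[j];
        const double d = dy * dy + dx * dx;
        if (d < b1) {
          b2 = b1; j2 = j1;
          b1 = d;  j1 = j;
        } else if (d < b2) {
          b2 = d; j2 = j;
        }
      }
      i1[p] = j1 + 1;
      i2[p] = j2 + 1;
      d1[p] = std::sqrt(b1);
    }
  }
  return List::create(_["i1"] = i1, _["i2"] = i2, _["d1"] = d1);
}
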