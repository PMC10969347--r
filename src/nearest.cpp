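#include <Rcpp.h>
using namespace Rcpp;

// Brute-force nearest neighbor: for each row of x, the index (1-based) of
// the nearest row of y and the squared Euclidean distance.  Ties resolve to
// the lowest index.
// [[Rcpp::export(name = ".nn_bruteforce")]]
List nn_bruteforce(NumericMatrix x, NumericMatrix y) {
  const int n1 = x.nrow(), n2 = y.nrow();
  IntegerVector idx(n1);
  NumericVector d2(n1);
  const double *xp = REAL(x), *yp = REAL(y);
  for (int i = 0; i < n1; ++i) {
    const double xi0 = xp[i], xi1 = xp[i + n1], xi2 = xp[i + 2 * n1];
    double best = R_PosInf;
    int bj = 0;
    for (int j = 0; j < n2; ++j) {
      const double dx = xi0 - yp[j];
      const double dy = xi1 - yp[j + n2];
      const double dz = xi2 - yp[j + 2 * n2];
      // accumulate the three squares in extended precision, as R's sum()
      // does, so distances match an R-level recomputation bit for bit
      const double s = (double)((long double)(dx * dx) + (dy * dy) + (dz * dz));
      if (s < best) { best = s; bj = j; }
    }
    idx[i] = bj + 1;
    d2[i] = best;
  }
  return List::create(_["index"] = idx, _["dist2"] = d2);
}
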