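// Minimum Euclidean distances between border-voxel point sets, used by
// the signed average surface distance. O(n*m) over border sets, which
// stay small (surfaces, not volumes).

#include <Rcpp.h>

using namespace Rcpp;

// from, to: k x 3 matrices of physical voxel-centre coordinates (mm).
// Returns for each row of `from` the distance to the nearest row of `to`.
// [[Rcpp::export]]
NumericVector min_pairwise_dist_cpp(NumericMatrix from, NumericMatrix to) {
  const int n = from.nrow(), m = to.nrow();
  if (m == 0) stop("empty target point set");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double x = from(i, 0), y = from(i, 1), z = from(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dx = x - to(j, 0), dy = y - to(j, 1), dz = z - to(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
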