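#include <Rcpp.h>
using namespace Rcpp;

// All-pairs shortest paths by Floyd-Warshall with shortest-path counts.
// `w` is a symmetric matrix of edge weights with NA (or Inf) where no edge
// exists; the diagonal is ignored. Path-length ties are resolved under an
// absolute tolerance so equal-length alternatives through floating-point
// weights are counted as distinct shortest paths.
// [[Rcpp::export(name = ".fw_core")]]
List fw_core(NumericMatrix w, double tol) {
  int n = w.nrow();
  NumericMatrix d(n, n);
  NumericMatrix sigma(n, n);

  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i == j) {
        d(i, j) = 0.0;
        sigma(i, j) = 1.0;
      } else {
        double wij = w(i, j);
        if (NumericMatrix::is_na(wij) || wij == R_PosInf) {
          d(i, j) = R_PosInf;
          sigma(i, j) = 0.0;
        } else {
          if (wij < 0) stop("negative edge weight");
          d(i, j) = wij;
          sigma(i, j) = 1.0;
        }
      }
    }
  }

  for (int k = 0; k < n; ++k) {
    for (int i = 0; i < n; ++i) {
      if (i == k || d(i, k) == R_PosInf) continue;
      double dik = d(i, k);
      double sik = sigma(i, k);
      for (int j = 0; j < n; ++j) {
        if (j == k || j == i || d(k, j) == R_PosInf) continue;
        double alt = dik + d(k, j);
        if (alt < d(i, j) - tol) {
          d(i, j) = alt;
          sigma(i, j) = sik * sigma(k, j);
        } else if (alt <= d(i, j) + tol) {
          sigma(i, j) += sik * sigma(k, j);
        }
      }
    }
  }

  return List::create(_["d"] = d, _["sigma"] = sigma);
}
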