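#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// clearance of query points against a set of atoms:
// out[i] = min_j ( |p_i - a_j| - vdw_j )
// Atoms are scanned outward from the query's z, pruning once the axial
// distance alone exceeds the best clearance found so far.
// [[Rcpp::export]]
NumericVector clearance_cpp(NumericMatrix points, NumericMatrix atoms,
                            NumericVector vdw) {
  const int n = points.nrow(), m = atoms.nrow();
  NumericVector out(n);
  if (m == 0) {
    std::fill(out.begin(), out.end(), R_PosInf);
    return out;
  }
  // sort atoms by z
  std::vector<int> ord(m);
  for (int j = 0; j < m; ++j) ord[j] = j;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return atoms(a, 2) < atoms(b, 2);
  });
  std::vector<double> ax(m), ay(m), az(m), ar(m);
  double rmax = 0.0;
  for (int j = 0; j < m; ++j) {
    ax[j] = atoms(ord[j], 0);
    ay[j] = atoms(ord[j], 1);
    az[j] = atoms(ord[j], 2);
    ar[j] = vdw[ord[j]];
    if (ar[j] > rmax) rmax = ar[j];
  }
  for (int i = 0; i < n; ++i) {
    const double px = points(i, 0), py = points(i, 1), pz = points(i, 2);
    // first atom with z >= pz
    int hi = std::lower_bound(az.begin(), az.end(), pz) - az.begin();
    int lo = hi - 1;
    double best = R_PosInf;
    while (lo >= 0 || hi < m) {
      int j;
      if (lo < 0) j = hi++;
      else if (hi >= m) j = lo--;
      else if (pz - az[lo] < az[hi] - pz) j = lo--;
      else j = hi++;
      const double dz = pz - az[j];
      if (std::abs(dz) - rmax >= best) break;  // no closer atom possible
      const double dx = px - ax[j], dy = py - ay[j];
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz) - ar[j];
      if (d < best) best = d;
    }
    out[i] = best;
  }
  return out;
}
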