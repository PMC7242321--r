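#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// First-order partial correlation of (x,y) given z from the three pairwise
// Pearson correlations. Caller guarantees |rxz| < 1 and |ryz| < 1.
static inline double partial_cor(double rxy, double rxz, double ryz) {
  return (rxy - rxz * ryz) / std::sqrt((1.0 - rxz * rxz) * (1.0 - ryz * ryz));
}

// PCIT significance over a correlation matrix.
//
// For every unordered trio (x,y,z) the three first-order partial
// correlations are computed and the information-theory tolerance
//   eps = mean over valid pairs of (partial / direct)
// is formed; ratio terms whose direct correlation is exactly 0 are dropped
// (a trio with all three directs 0 rejects nothing). Edge (x,y) is locally
// rejected by z iff |r_xy| <= |eps * r_xz| and |r_xy| <= |eps * r_yz|.
// A trio containing a perfect correlation (|r| >= 1 - tol) is skipped:
// partial correlations are undefined there and perfect edges are kept.
// An edge is significant iff |r| > 0 and no third node rejects it.
//
// `subset` (0-based, sorted unique) optionally restricts both the edges
// tested and the conditioning nodes to a subset; trios are streamed, never
// materialised, so memory stays O(n^2).
// [[Rcpp::export(name = ".pcit_kernel")]]
LogicalMatrix pcit_kernel(NumericMatrix C, IntegerVector subset) {
  const int n = C.nrow();
  if (C.ncol() != n) stop("correlation matrix must be square");
  const double one_tol = 1.0 - 1e-12;

  std::vector<int> idx;
  if (subset.size() == 0) {
    idx.resize(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
  } else {
    idx.assign(subset.begin(), subset.end());
    for (size_t i = 0; i < idx.size(); ++i)
      if (idx[i] < 0 || idx[i] >= n) stop("subset index out of range");
  }
  const int m = (int) idx.size();
  if (m < 3) stop("PCIT needs at least 3 nodes");

  LogicalMatrix sig(n, n);
  // start: all candidate edges within the subset with |r| > 0 significant
  for (int a = 0; a < m; ++a)
    for (int b = a + 1; b < m; ++b) {
      bool s = std::fabs(C(idx[a], idx[b])) > 0.0;
      sig(idx[a], idx[b]) = s;
      sig(idx[b], idx[a]) = s;
    }

  for (int a = 0; a < m; ++a) {
    const int x = idx[a];
    for (int b = a + 1; b < m; ++b) {
      const int y = idx[b];
      const double rxy = C(x, y);
      for (int c = b + 1; c < m; ++c) {
        const int z = idx[c];
        const double rxz = C(x, z);
        const double ryz = C(y, z);

        if (std::fabs(rxy) >= one_tol || std::fabs(rxz) >= one_tol ||
            std::fabs(ryz) >= one_tol)
          continue;  // degenerate trio: skipped for rejection purposes

        const double pxy = partial_cor(rxy, rxz, ryz);
        const double pxz = partial_cor(rxz, rxy, ryz);
        const double pyz = partial_cor(ryz, rxy, rxz);

        double s = 0.0;
        int k = 0;
        if (rxy != 0.0) { s += pxy / rxy; ++k; }
        if (rxz != 0.0) { s += pxz / rxz; ++k; }
        if (ryz != 0.0) { s += pyz / ryz; ++k; }
        if (k == 0) continue;  // all three directs zero: rejects nothing
        const double eps = s / k;

        const double exy = std::fabs(eps * rxy);
        const double exz = std::fabs(eps * rxz);
        const double eyz = std::fabs(eps * ryz);

        if (std::fabs(rxy) <= exz && std::fabs(rxy) <= eyz) {
          sig(x, y) = false; sig(y, x) = false;
        }
        if (std::fabs(rxz) <= exy && std::fabs(rxz) <= eyz) {
          sig(x, z) = false; sig(z, x) = false;
        }
        if (std::fabs(ryz) <= exy && std::fabs(ryz) <= exz) {
          sig(y, z) = false; sig(z, y) = false;
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return sig;
}
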