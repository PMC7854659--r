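#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trio-wise PCIT elimination. For each trio (x, y, z) the three first-order
// partial correlations are computed, the local tolerance is the mean of the
// signed ratios partial/direct (ratio forced to 1 when |direct| < 1e-12 or
// the partial is undefined), and a pair is flagged non-significant when its
// direct correlation is dominated, through the tolerance, by both flanking
// correlations. A degenerate denominator (|flanking r| = 1) counts as
// maximal redundancy and eliminates the pair outright.
// [[Rcpp::export]]
LogicalMatrix pcit_elim_cpp(NumericMatrix R) {
  const int n = R.nrow();
  const double tiny = 1e-12;
  LogicalMatrix elim(n, n);

  for (int x = 0; x < n - 2; ++x) {
    for (int y = x + 1; y < n - 1; ++y) {
      const double rxy = R(x, y);
      for (int z = y + 1; z < n; ++z) {
        const double rxz = R(x, z);
        const double ryz = R(y, z);

        const double dxy = (1.0 - rxz * rxz) * (1.0 - ryz * ryz);
        const double dxz = (1.0 - rxy * rxy) * (1.0 - ryz * ryz);
        const double dyz = (1.0 - rxy * rxy) * (1.0 - rxz * rxz);

        double t1 = 1.0, t2 = 1.0, t3 = 1.0;
        if (dxy > 0.0 && std::fabs(rxy) >= tiny)
          t1 = ((rxy - rxz * ryz) / std::sqrt(dxy)) / rxy;
        if (dxz > 0.0 && std::fabs(rxz) >= tiny)
          t2 = ((rxz - rxy * ryz) / std::sqrt(dxz)) / rxz;
        if (dyz > 0.0 && std::fabs(ryz) >= tiny)
          t3 = ((ryz - rxy * rxz) / std::sqrt(dyz)) / ryz;
        const double eps = (t1 + t2 + t3) / 3.0;

        bool exy, exz, eyz;
        if (dxy <= 0.0) exy = true;
        else exy = std::fabs(rxy) <= std::fabs(eps * rxz) &&
                   std::fabs(rxy) <= std::fabs(eps * ryz);
        if (dxz <= 0.0) exz = true;
        else exz = std::fabs(rxz) <= std::fabs(eps * rxy) &&
                   std::fabs(rxz) <= std::fabs(eps * ryz);
        if (dyz <= 0.0) eyz = true;
        else eyz = std::fabs(ryz) <= std::fabs(eps * rxy) &&
                   std::fabs(ryz) <= std::fabs(eps * rxz);

        if (exy) { elim(x, y) = true; elim(y, x) = true; }
        if (exz) { elim(x, z) = true; elim(z, x) = true; }
        if (eyz) { elim(y, z) = true; elim(z, y) = true; }
      }
    }
  }
  return elim;
}
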