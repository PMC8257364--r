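#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Counterpropagation training loop. All randomness (prototype init and the
// concatenated per-epoch presentation orders) is drawn in R and passed in,
// so the loop itself is fully deterministic. Arithmetic deliberately mirrors
// a plain double-precision loop (squared differences accumulated in input
// order, strict '<' argmin keeping the lowest index) so a naive R reference
// replays it bit-for-bit.
// [[Rcpp::export]]
List cpn_train_cpp(NumericMatrix X, NumericVector d, NumericMatrix W0,
                   NumericVector z0, IntegerVector order, NumericVector alpha,
                   NumericVector gamma, NumericVector radius,
                   NumericMatrix lat) {
  const int n_pres = order.size();
  const int units = W0.nrow();
  const int k = W0.ncol();
  NumericMatrix W = clone(W0);
  NumericVector z = clone(z0);

  for (int t = 0; t < n_pres; ++t) {
    const int r = order[t];
    int winner = 0;
    double best = R_PosInf;
    for (int l = 0; l < units; ++l) {
      double s = 0.0;
      for (int j = 0; j < k; ++j) {
        const double diff = X(r, j) - W(l, j);
        s += diff * diff;
      }
      const double net = std::sqrt(s);
      if (net < best) {
        best = net;
        winner = l;
      }
    }
    const double a = alpha[t];
    const double g = gamma[t];
    const double rad = radius[t];
    for (int l = 0; l < units; ++l) {
      if (lat(winner, l) <= rad) {
        for (int j = 0; j < k; ++j) {
          W(l, j) += a * (X(r, j) - W(l, j));
        }
      }
    }
    z[winner] += g * (d[r] - z[winner]);
  }
  return List::create(_["w"] = W, _["z"] = z);
}
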