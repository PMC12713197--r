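#include <Rcpp.h>
using namespace Rcpp;

// Per-column change-score moments for one simulated arm.
//
// Reproduces, column by column and bit for bit, the R reference computation
//   post = pre + w * eps (+ shift[j] in column j)
//   d    = post - pre
//   m    = sum(d) / n          (long-double accumulation, as base sum())
//   ss   = sum((d - m)^2)      (double intermediates, long-double accumulation)
// without materialising any n x R temporaries. shift may be length 0 (no
// treatment effect) or length R (per-replicate additive effect).
//
// [[Rcpp::export(name = ".cell_moments")]]
List cell_moments(NumericMatrix pre, NumericMatrix eps, double w,
                  NumericVector shift) {
  const int n = pre.nrow();
  const int R = pre.ncol();
  if (eps.nrow() != n || eps.ncol() != R)
    stop("pre and eps must have identical dimensions");
  const bool has_shift = shift.size() > 0;
  if (has_shift && shift.size() != R)
    stop("shift must be empty or have one entry per column");

  NumericVector mean_change(R), ss_change(R);
  std::vector<double> d(n);
  for (int j = 0; j < R; ++j) {
    const double* pc = &pre(0, j);
    const double* ec = &eps(0, j);
    const double sj = has_shift ? shift[j] : 0.0;
    long double acc = 0.0L;
    for (int i = 0; i < n; ++i) {
      double post = pc[i] + w * ec[i];
      if (sj != 0.0) post += sj;
      d[i] = post - pc[i];
      acc += d[i];
    }
    const double m = (double)acc / n;
    long double acc2 = 0.0L;
    for (int i = 0; i < n; ++i) {
      const double dd = d[i] - m;
      acc2 += dd * dd;
    }
    mean_change[j] = m;
    ss_change[j] = (double)acc2;
  }
  return List::create(_["mean_change"] = mean_change,
                      _["ss_change"] = ss_change);
}
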