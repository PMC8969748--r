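#include <Rcpp.h>
using namespace Rcpp;

// One-pole asymmetric smoother: rises with the attack coefficient when the
// input exceeds the current state, falls with the release coefficient
// otherwise. Coefficients are per-sample pole magnitudes a = exp(-1/(fs*tau)).
// `init` seeds the state; NA means "start at the first input sample" (avoids
// a spurious onset transient when the signal starts in steady state).
// [[Rcpp::export]]
NumericVector asym_smooth(NumericVector x, double a_att, double a_rel,
                          double init = NA_REAL) {
  R_xlen_t n = x.size();
  NumericVector y(n);
  if (n == 0) return y;
  double s = NumericVector::is_na(init) ? x[0] : init;
  for (R_xlen_t i = 0; i < n; ++i) {
    double a = (x[i] > s) ? a_att : a_rel;
    s = a * s + (1.0 - a) * x[i];
    y[i] = s;
  }
  return y;
}
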