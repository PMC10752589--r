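#include <Rcpp.h>
using namespace Rcpp;

// Per-time-step center/surround RF recursion with adaptation, vectorized
// over cells (columns). Mirrors the documented update rules exactly; see
// R/rf_model.R for the scientific description.

// [[Rcpp::export]]
List bc_recursion_cpp(NumericMatrix ac, NumericMatrix as,
                      NumericVector rise_c, NumericVector dec_c,
                      NumericVector rise_s, NumericVector str_s,
                      NumericVector rev_s, NumericVector amp,
                      double r_in) {
  const int n_t = ac.nrow(), n_c = ac.ncol();
  NumericMatrix rc(n_t, n_c), ad(n_t, n_c), rs(n_t, n_c), rf(n_t, n_c);
  for (int j = 0; j < n_c; ++j) {
    double rc_p = 0.0, ad_p = 1.0, rs_p = 0.0;
    const double rcj = rise_c[j] < 1.0 ? 1.0 : rise_c[j];
    const double dcj = dec_c[j] < 1.0 ? 1.0 : dec_c[j];
    const double rsj = rise_s[j] < 1.0 ? 1.0 : rise_s[j];
    for (int i = 0; i < n_t; ++i) {
      double rc_i = (rc_p + (ac(i, j) - rc_p) / rcj) * ad_p;
      double ad_i = ad_p - rc_i / dcj;
      if (ad_i < 0.0) ad_i = 0.0;
      double rs_i = rs_p + (as(i, j) * str_s[j] - rs_p) / rsj;
      rc(i, j) = rc_i; ad(i, j) = ad_i; rs(i, j) = rs_i;
      rf(i, j) = amp[j] * (rc_i + rs_i * rev_s[j]) / (rc_i + rs_i + r_in);
      rc_p = rc_i; ad_p = ad_i; rs_p = rs_i;
    }
  }
  return List::create(_["rf_center"] = rc, _["adaptation"] = ad,
                      _["rf_surround"] = rs, _["rf_full"] = rf);
}
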