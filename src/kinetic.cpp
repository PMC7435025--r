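#include "kinetic.h"
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector irf_eval_cpp(NumericVector t, double F, double t0,
                           double minTT, double E, double k) {
  const int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = ath_irf(t[i], F, t0, minTT, E, k);
  return out;
}

// [[Rcpp::export]]
arma::vec forward_model_cpp(const arma::vec& aif, double dt, double F,
                            double t0, double minTT, double E, double k) {
  const int n = aif.n_elem;
  arma::vec irf(n), tc(n);
  ath_irf_lags(irf, n, dt, F, t0, minTT, E, k);
  causal_conv(tc, aif, irf, dt);
  return tc;
}

// Forward model for a whole stack of voxels: params is n_vox x 5
// (F, t0, minTT, E, k). Returns n_vox x n matrix of tissue curves.
// [[Rcpp::export]]
arma::mat forward_model_stack_cpp(const arma::mat& params,
                                  const arma::vec& aif, double dt) {
  const int n = aif.n_elem;
  const int nv = params.n_rows;
  arma::mat out(nv, n);
  arma::vec irf(n), tc(n);
  for (int v = 0; v < nv; ++v) {
    ath_irf_lags(irf, n, dt, params(v, 0), params(v, 1), params(v, 2),
                 params(v, 3), params(v, 4));
    causal_conv(tc, aif, irf, dt);
    out.row(v) = tc.t();
  }
  return out;
}
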