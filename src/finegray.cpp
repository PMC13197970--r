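// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Weighted Fine-Gray partial likelihood quantities (Breslow ties).
//
// Subjects must be sorted by follow-up time ascending. The risk set at a
// cause-1 event time t_k contains (a) subjects with T_i >= t_k (IPCW weight 1)
// and (b) subjects with a competing event at T_i < t_k, carried forward with
// weight G(t_k-)/G(T_i-) where G is the censoring Kaplan-Meier. Suffix sums for
// (a) are obtained as total-minus-prefix, so one ascending sweep yields the
// log-likelihood, score and information in O(n p^2).
//
// status: 0 censored, 1 event of interest, 2 competing event.
// ginv:   1/G(T_i-) per subject (only used when status == 2).
// tev:    distinct cause-1 event times, ascending; gtev: G(t_k-).
// [[Rcpp::export]]
List fg_quantities_cpp(NumericVector time, IntegerVector status, arma::mat X,
                       arma::vec beta, NumericVector ginv, NumericVector tev,
                       NumericVector gtev, bool resid = false) {
  const int n = X.n_rows, p = X.n_cols, K = tev.size();
  arma::vec eta = X * beta;
  arma::vec r = arma::exp(eta);

  // totals over all subjects (for suffix sums of risk-set part (a))
  double tot0 = arma::accu(r);
  arma::vec tot1 = X.t() * r;
  arma::mat tot2(p, p, arma::fill::zeros);
  for (int i = 0; i < n; ++i) tot2 += r[i] * (X.row(i).t() * X.row(i));

  // prefix accumulators: P* over subjects with T_i < t_k (all statuses),
  // C* over competing subjects with T_i < t_k weighted by 1/G(T_i-)
  double P0 = 0.0, C0 = 0.0;
  arma::vec P1(p, arma::fill::zeros), C1(p, arma::fill::zeros);
  arma::mat P2(p, p, arma::fill::zeros), C2(p, p, arma::fill::zeros);

  double nll = 0.0;
  arma::vec grad(p, arma::fill::zeros);
  arma::mat hess(p, p, arma::fill::zeros);
  NumericVector s0k(K), dk(K);
  arma::mat xbar(K, p, arma::fill::zeros);

  int i = 0;          // pointer over subjects (ascending time)
  int ev_lo = 0;      // pointer for locating event subjects of each t_k
  for (int k = 0; k < K; ++k) {
    const double tk = tev[k];
    while (i < n && time[i] < tk) {
      P0 += r[i]; P1 += r[i] * X.row(i).t(); P2 += r[i] * (X.row(i).t() * X.row(i));
      if (status[i] == 2) {
        const double rw = r[i] * ginv[i];
        C0 += rw; C1 += rw * X.row(i).t(); C2 += rw * (X.row(i).t() * X.row(i));
      }
      ++i;
    }
    const double g = gtev[k];
    const double S0 = (tot0 - P0) + g * C0;
    arma::vec S1 = (tot1 - P1) + g * C1;
    arma::mat S2 = (tot2 - P2) + g * C2;
    arma::vec xb = S1 / S0;

    // events at t_k
    double d = 0.0;
    while (ev_lo < n && time[ev_lo] < tk) ++ev_lo;
    int j = ev_lo;
    while (j < n && time[j] == tk) {
      if (status[j] == 1) {
        d += 1.0;
        nll -= eta[j];
        grad -= X.row(j).t();
      }
      ++j;
    }
    nll += d * std::log(S0);
    grad += d * xb;
    hess += d * (S2 / S0 - xb * xb.t());
    s0k[k] = S0; dk[k] = d;
    xbar.row(k) = xb.t();
  }

  List out = List::create(_["nll"] = nll, _["grad"] = grad, _["hess"] = hess,
                          _["s0"] = s0k, _["dk"] = dk);
  if (resid) {
    // per-subject score residuals for the clustered sandwich variance
    NumericVector cum0(K);
    arma::mat cum1(K, p, arma::fill::zeros);
    NumericVector ccum0(K);
    arma::mat ccum1(K, p, arma::fill::zeros);
    double a0 = 0.0; arma::vec a1(p, arma::fill::zeros);
    for (int k = 0; k < K; ++k) {
      a0 += dk[k] / s0k[k];
      a1 += (dk[k] / s0k[k]) * xbar.row(k).t();
      cum0[k] = a0; cum1.row(k) = a1.t();
    }
    double b0 = 0.0; arma::vec b1(p, arma::fill::zeros);
    for (int k = K - 1; k >= 0; --k) {
      b0 += gtev[k] * dk[k] / s0k[k];
      b1 += (gtev[k] * dk[k] / s0k[k]) * xbar.row(k).t();
      ccum0[k] = b0; ccum1.row(k) = b1.t();
    }
    arma::mat U(n, p, arma::fill::zeros);
    int kI = -1; // last event time index with tev <= T_i
    int ii = 0;
    for (int s = 0; s < n; ++s) {
      while (kI + 1 < K && tev[kI + 1] <= time[s]) ++kI;
      arma::vec u(p, arma::fill::zeros);
      if (status[s] == 1) {
        // locate the event-time row (tev[kI] == time[s] by construction)
        u += X.row(s).t() - xbar.row(kI).t();
      }
      if (kI >= 0) {
        u -= r[s] * (X.row(s).t() * cum0[kI] - cum1.row(kI).t());
      }
      if (status[s] == 2 && kI + 1 < K) {
        u -= r[s] * ginv[s] *
             (X.row(s).t() * ccum0[kI + 1] - ccum1.row(kI + 1).t());
      }
      U.row(s) = u.t();
      (void)ii;
    }
    out["resid"] = U;
  }
  return out;
}
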