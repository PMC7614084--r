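// Weighted EM for Gaussian mixtures (log-Ks space) and for the
// exponential-lognormal mixture. Node weights enter as fractional
// observation counts. The R wrappers own initialization, restarts, BIC and
// component pruning; these loops only iterate E/M to convergence.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export]]
List wem_gmm_cpp(NumericVector x, NumericVector w, NumericVector m0,
                 NumericVector s0, NumericVector pi0, double tol = 1e-8,
                 int maxit = 500) {
  int n = x.size(), k = m0.size();
  NumericVector m = clone(m0), s = clone(s0), pi = clone(pi0);
  double n_eff = sum(w);
  double ll_old = R_NegInf;
  bool monotone = true, converged = false;
  NumericMatrix r(n, k);
  NumericVector wk(k);
  double ll = R_NegInf;
  int it;
  for (it = 0; it < maxit; ++it) {
    // E step and log-likelihood
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double rowsum = 0.0;
      for (int j = 0; j < k; ++j) {
        double z = (x[i] - m[j]) / s[j];
        double d = pi[j] * std::exp(-0.5 * z * z) / (s[j] * 2.5066282746310002);
        r(i, j) = d;
        rowsum += d;
      }
      if (rowsum < 1e-300) rowsum = 1e-300;
      ll += w[i] * std::log(rowsum);
      for (int j = 0; j < k; ++j) r(i, j) /= rowsum;
    }
    if (ll < ll_old - 1e-8) monotone = false;
    if (R_finite(ll_old) && std::fabs(ll - ll_old) < tol * (std::fabs(ll_old) + 1)) {
      converged = true;
      break;
    }
    ll_old = ll;
    // M step
    for (int j = 0; j < k; ++j) {
      double wj = 0.0, mj = 0.0;
      for (int i = 0; i < n; ++i) wj += w[i] * r(i, j);
      wk[j] = wj;
      if (wj < 1e-8 * n_eff) continue;  // collapsed: handled by the R wrapper
      for (int i = 0; i < n; ++i) mj += w[i] * r(i, j) * x[i];
      mj /= wj;
      double vj = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = x[i] - mj;
        vj += w[i] * r(i, j) * d * d;
      }
      vj /= wj;
      if (vj < 1e-6) vj = 1e-6;
      m[j] = mj;
      s[j] = std::sqrt(vj);
      pi[j] = wj / n_eff;
    }
    double pisum = sum(pi);
    for (int j = 0; j < k; ++j) pi[j] /= pisum;
    bool collapsed = false;
    for (int j = 0; j < k; ++j) if (wk[j] < 1e-8 * n_eff) collapsed = true;
    if (collapsed) {
      return List::create(_["collapsed"] = true, _["wk"] = wk, _["m"] = m,
                          _["s"] = s, _["pi"] = pi, _["loglik"] = ll,
                          _["converged"] = false, _["monotone"] = monotone);
    }
  }
  return List::create(_["collapsed"] = false, _["m"] = m, _["s"] = s,
                      _["pi"] = pi, _["loglik"] = ll_old,
                      _["converged"] = converged, _["monotone"] = monotone);
}

// [[Rcpp::export]]
List wem_expln_cpp(NumericVector x, NumericVector lx, NumericVector w,
                   double rate0, NumericVector ml0, NumericVector sl0,
                   NumericVector pi0, double tol = 1e-8, int maxit = 500) {
  int n = x.size(), j = ml0.size();
  double rate = rate0;
  NumericVector ml = clone(ml0), sl = clone(sl0), pi = clone(pi0); // pi[0]=exp
  double n_eff = sum(w);
  double ll_old = R_NegInf, ll = R_NegInf;
  bool monotone = true, converged = false;
  NumericMatrix r(n, j + 1);
  for (int it = 0; it < maxit; ++it) {
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double rowsum = 0.0;
      double de = pi[0] * rate * std::exp(-rate * x[i]);
      r(i, 0) = de; rowsum += de;
      for (int c = 0; c < j; ++c) {
        double z = (lx[i] - ml[c]) / sl[c];
        double d = pi[c + 1] * std::exp(-0.5 * z * z) /
                   (x[i] * sl[c] * 2.5066282746310002);
        r(i, c + 1) = d; rowsum += d;
      }
      if (rowsum < 1e-300) rowsum = 1e-300;
      ll += w[i] * std::log(rowsum);
      for (int c = 0; c <= j; ++c) r(i, c) /= rowsum;
    }
    if (ll < ll_old - 1e-8) monotone = false;
    if (R_finite(ll_old) && std::fabs(ll - ll_old) < tol * (std::fabs(ll_old) + 1)) {
      converged = true;
      break;
    }
    ll_old = ll;
    double w0 = 0.0, sx = 0.0;
    for (int i = 0; i < n; ++i) { w0 += w[i] * r(i, 0); sx += w[i] * r(i, 0) * x[i]; }
    if (w0 > 1e-10 && sx > 0) rate = w0 / sx;
    double tot = w0;
    for (int c = 0; c < j; ++c) {
      double wc = 0.0, mc = 0.0;
      for (int i = 0; i < n; ++i) wc += w[i] * r(i, c + 1);
      if (wc > 1e-10 * n_eff) {
        for (int i = 0; i < n; ++i) mc += w[i] * r(i, c + 1) * lx[i];
        mc /= wc;
        double vc = 0.0;
        for (int i = 0; i < n; ++i) {
          double d = lx[i] - mc;
          vc += w[i] * r(i, c + 1) * d * d;
        }
        vc /= wc;
        if (vc < 1e-6) vc = 1e-6;
        ml[c] = mc;
        sl[c] = std::sqrt(vc);
      }
      pi[c + 1] = std::max(wc, 1e-12);
      tot += pi[c + 1];
    }
    pi[0] = std::max(w0, 1e-12);
    tot = pi[0];
    for (int c = 0; c < j; ++c) tot += pi[c + 1];
    for (int c = 0; c <= j; ++c) pi[c] /= tot;
  }
  return List::create(_["rate"] = rate, _["meanlog"] = ml, _["sdlog"] = sl,
                      _["pi"] = pi, _["loglik"] = ll_old,
                      _["converged"] = converged, _["monotone"] = monotone);
}
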