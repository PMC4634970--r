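// Kalman filtering / RTS smoothing kernel for linear-Gaussian state-space
// models whose observations are scalar pseudo-measurements (population
// center of mass) with known time-varying variances.  This is the hot loop
// of the EM benchmarks (many restarts over 40 x 1000-step data sets), hence
// compiled.  Conventions:
//   y, v : T x p matrices of observations and their variances; a non-finite
//          entry in either marks a missing observation (prediction only).
//   H    : p x n observation matrix (given, never learned).
//   wrapL: length-p vector; if wrapL[j] > 0 the j-th observation lives on a
//          circle of that circumference and is unwrapped to the branch
//          nearest the predicted value before the update.
//   Ups0 : prior covariance; +Inf on a diagonal entry requests a diffuse
//          (zero-precision) prior for that state direction, handled in
//          information form at t = 0 (the log-likelihood then skips t = 0).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat safe_inv(const mat& A) {
  mat Ai;
  if (!inv_sympd(Ai, symmatu(A))) {
    if (!inv(Ai, symmatu(A))) Ai = pinv(symmatu(A));
  }
  return Ai;
}

// [[Rcpp::export]]
Rcpp::List kf_rts_cpp(const arma::mat& Gamma, const arma::vec& mu,
                      const arma::mat& Sigma, const arma::vec& nu0,
                      const arma::mat& Ups0, const arma::mat& H,
                      const arma::mat& y, const arma::mat& v,
                      const arma::vec& wrapL, bool smooth) {
  const uword T = y.n_rows, p = y.n_cols, n = Gamma.n_rows;
  mat m_pred(n, T), m_filt(n, T);
  cube P_pred(n, n, T), P_filt(n, n, T);
  double loglik = 0.0;
  const double LOG2PI = std::log(2.0 * M_PI);
  bool diffuse = !Ups0.is_finite();

  vec m(n);
  mat P(n, n);

  for (uword t = 0; t < T; ++t) {
    if (t == 0) {
      if (diffuse) {
        // information form: zero precision along diffuse directions
        vec d = Ups0.diag();
        mat lam = zeros<mat>(n, n);
        for (uword i = 0; i < n; ++i)
          lam(i, i) = std::isinf(d(i)) ? 0.0 : 1.0 / d(i);
        vec eta = lam * nu0;
        for (uword j = 0; j < p; ++j) {
          double yj = y(0, j), vj = v(0, j);
          if (!std::isfinite(yj) || !std::isfinite(vj)) continue;
          vec h = H.row(j).t();
          lam += h * h.t() / vj;
          eta += h * yj / vj;
        }
        lam.diag() += 1e-12;  // directions never observed stay near-diffuse
        P = safe_inv(lam);
        m = P * eta;
      } else {
        m = nu0;
        P = Ups0;
        for (uword j = 0; j < p; ++j) {
          double yj = y(0, j), vj = v(0, j);
          if (!std::isfinite(yj) || !std::isfinite(vj)) continue;
          rowvec h = H.row(j);
          double pred = as_scalar(h * m);
          if (wrapL(j) > 0.0)
            yj -= wrapL(j) * std::round((yj - pred) / wrapL(j));
          double S = as_scalar(h * P * h.t()) + vj;
          vec K = P * h.t() / S;
          double e = yj - pred;
          m += K * e;
          P = symmatu(P - K * (h * P));
          loglik += -0.5 * (LOG2PI + std::log(S) + e * e / S);
        }
      }
      m_pred.col(0) = m;  P_pred.slice(0) = P;  // prior at t = 0
    } else {
      m = Gamma * m + mu;
      P = symmatu(Gamma * P * Gamma.t() + Sigma);
      m_pred.col(t) = m;
      P_pred.slice(t) = P;
      for (uword j = 0; j < p; ++j) {
        double yj = y(t, j), vj = v(t, j);
        if (!std::isfinite(yj) || !std::isfinite(vj)) continue;
        rowvec h = H.row(j);
        double pred = as_scalar(h * m);
        if (wrapL(j) > 0.0)
          yj -= wrapL(j) * std::round((yj - pred) / wrapL(j));
        double S = as_scalar(h * P * h.t()) + vj;
        double e = yj - pred;
        vec K = P * h.t() / S;
        m += K * e;
        P = symmatu(P - K * (h * P));
        loglik += -0.5 * (LOG2PI + std::log(S) + e * e / S);
      }
    }
    m_filt.col(t) = m;
    P_filt.slice(t) = P;
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("mean") = m_filt.t(),
    Rcpp::Named("cov") = P_filt,
    Rcpp::Named("pred_mean") = m_pred.t(),
    Rcpp::Named("pred_cov") = P_pred,
    Rcpp::Named("loglik") = loglik,
    Rcpp::Named("diffuse") = diffuse);

  if (smooth && T >= 1) {
    mat m_s(n, T);
    cube P_s(n, n, T), Ccross(n, n, (T > 1) ? T - 1 : 1, fill::zeros);
    m_s.col(T - 1) = m_filt.col(T - 1);
    P_s.slice(T - 1) = P_filt.slice(T - 1);
    for (uword t = T - 1; t-- > 0;) {
      mat J = P_filt.slice(t) * Gamma.t() * safe_inv(P_pred.slice(t + 1));
      m_s.col(t) = m_filt.col(t) +
        J * (m_s.col(t + 1) - m_pred.col(t + 1));
      P_s.slice(t) = symmatu(P_filt.slice(t) +
        J * (P_s.slice(t + 1) - P_pred.slice(t + 1)) * J.t());
      // cov(x_{t+1}, x_t | all data)
      Ccross.slice(t) = P_s.slice(t + 1) * J.t();
    }
    out["smooth_mean"] = m_s.t();
    out["smooth_cov"] = P_s;
    out["cross_cov"] = Ccross;
  }
  return out;
}
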