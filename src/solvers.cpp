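#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for linear models, after the LIBLINEAR family of
// solvers (Hsieh et al. 2008 for L1-loss SVC; Ho & Lin 2012 for L1-loss SVR).
// X is n x d and must already carry any bias column; passes are cyclic so the
// result is deterministic for a fixed input ordering.

// Linear epsilon-insensitive support vector regression:
//   min_w 0.5 ||w||^2 + C sum_i max(0, |w.x_i - y_i| - eps)
// Dual variable beta_i in [-C, C]; exact coordinate minimization is a
// soft-threshold step because the coordinate objective is quadratic + |.|.
// [[Rcpp::export]]
NumericVector svr_dcd(NumericMatrix X, NumericVector y, double C, double eps,
                      int max_iter, double tol) {
  const int n = X.nrow(), d = X.ncol();
  NumericVector w(d), beta(n), qdiag(n);
  for (int i = 0; i < n; ++i) {
    double q = 0.0;
    for (int j = 0; j < d; ++j) q += X(i, j) * X(i, j);
    qdiag[i] = q;
  }
  for (int it = 0; it < max_iter; ++it) {
    double max_step = 0.0;
    for (int i = 0; i < n; ++i) {
      if (qdiag[i] <= 0.0) continue;
      double g = -y[i];
      for (int j = 0; j < d; ++j) g += w[j] * X(i, j);
      // unpenalized coordinate minimizer, then soft-threshold by eps/Q_ii
      double z = beta[i] - g / qdiag[i];
      double thr = eps / qdiag[i];
      double b_new;
      if (z > thr) b_new = z - thr;
      else if (z < -thr) b_new = z + thr;
      else b_new = 0.0;
      if (b_new > C) b_new = C;
      if (b_new < -C) b_new = -C;
      double delta = b_new - beta[i];
      if (delta != 0.0) {
        beta[i] = b_new;
        for (int j = 0; j < d; ++j) w[j] += delta * X(i, j);
        double step = std::abs(delta) * std::sqrt(qdiag[i]);
        if (step > max_step) max_step = step;
      }
    }
    if (max_step < tol) break;
  }
  return w;
}

// Linear L1-loss (hinge) support vector classification, y_i in {-1, +1}:
//   min_w 0.5 ||w||^2 + C sum_i max(0, 1 - y_i w.x_i)
// Dual variable alpha_i in [0, C]; exact coordinate update is a clamped
// Newton step.
// [[Rcpp::export]]
NumericVector svc_dcd(NumericMatrix X, NumericVector y, double C,
                      int max_iter, double tol) {
  const int n = X.nrow(), d = X.ncol();
  NumericVector w(d), alpha(n), qdiag(n);
  for (int i = 0; i < n; ++i) {
    double q = 0.0;
    for (int j = 0; j < d; ++j) q += X(i, j) * X(i, j);
    qdiag[i] = q;
  }
  for (int it = 0; it < max_iter; ++it) {
    double max_step = 0.0;
    for (int i = 0; i < n; ++i) {
      if (qdiag[i] <= 0.0) continue;
      double g = 0.0;
      for (int j = 0; j < d; ++j) g += w[j] * X(i, j);
      g = y[i] * g - 1.0;
      double a_new = alpha[i] - g / qdiag[i];
      if (a_new > C) a_new = C;
      if (a_new < 0.0) a_new = 0.0;
      double delta = a_new - alpha[i];
      if (delta != 0.0) {
        alpha[i] = a_new;
        for (int j = 0; j < d; ++j) w[j] += delta * y[i] * X(i, j);
        double step = std::abs(delta) * std::sqrt(qdiag[i]);
        if (step > max_step) max_step = step;
      }
    }
    if (max_step < tol) break;
  }
  return w;
}
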