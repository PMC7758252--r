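#include <Rcpp.h>
using namespace Rcpp;

// Two-variable SMO for the linear C-SVC dual:
//   min_a 0.5 a' Q a - e' a,  0 <= a_i <= C,  sum_i a_i y_i = 0,
// with Q_ij = y_i y_j <x_i, x_j>. Working pair = maximal violating pair,
// stopping when the KKT violation m(a) - M(a) drops below `tol` (the
// libsvm convention). Returns the primal weight vector and bias.
//
// [[Rcpp::export(name = ".svm_linear_smo")]]
List svm_linear_smo(NumericMatrix X, NumericVector y, double C,
                    double tol = 1e-3, int max_iter = 1000000) {
  const int n = X.nrow(), d = X.ncol();
  // Gram matrix (n is small in this pipeline: 40-42 rows)
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) s += X(i, k) * X(j, k);
      K[(size_t)i * n + j] = s;
      K[(size_t)j * n + i] = s;
    }
  }
  std::vector<double> alpha(n, 0.0);
  // u_i = sum_j alpha_j y_j K_ij (decision value without bias)
  std::vector<double> u(n, 0.0);
  int iter = 0;
  double m_up = 0.0, m_low = 0.0;
  for (; iter < max_iter; ++iter) {
    // maximal violating pair over -y_t grad_t = y_t - u_t (grad_t = y_t*u_t - 1)
    int i = -1, j = -1;
    m_up = -HUGE_VAL;
    m_low = HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      // grad_t = y_t u_t - 1, so -y_t grad_t = y_t - u_t
      double v = y[t] - u[t];
      bool in_up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool in_low = (y[t] < 0 && alpha[t] < C) || (y[t] > 0 && alpha[t] > 0);
      if (in_up && v > m_up) { m_up = v; i = t; }
      if (in_low && v < m_low) { m_low = v; j = t; }
    }
    if (i < 0 || j < 0 || m_up - m_low <= tol) break;
    // analytic two-variable update with box clipping
    double s = y[i] * y[j];
    double Ei = u[i] - y[i], Ej = u[j] - y[j];
    double eta = K[(size_t)i * n + i] + K[(size_t)j * n + j] -
                 2.0 * K[(size_t)i * n + j];
    if (eta <= 1e-12) eta = 1e-12;
    double L, H;
    if (s < 0) {
      L = std::max(0.0, alpha[j] - alpha[i]);
      H = std::min(C, C + alpha[j] - alpha[i]);
    } else {
      L = std::max(0.0, alpha[i] + alpha[j] - C);
      H = std::min(C, alpha[i] + alpha[j]);
    }
    double aj_new = alpha[j] + y[j] * (Ei - Ej) / eta;
    if (aj_new < L) aj_new = L;
    if (aj_new > H) aj_new = H;
    double ai_new = alpha[i] + s * (alpha[j] - aj_new);
    // snap float residue to the box so bound variables stay exactly bound
    const double snap = 1e-10 * (C > 1.0 ? C : 1.0);
    if (aj_new < snap) aj_new = 0.0; else if (aj_new > C - snap) aj_new = C;
    if (ai_new < snap) ai_new = 0.0; else if (ai_new > C - snap) ai_new = C;
    double dai = ai_new - alpha[i], daj = aj_new - alpha[j];
    if (std::fabs(dai) < 1e-15 && std::fabs(daj) < 1e-15) break;
    alpha[i] = ai_new;
    alpha[j] = aj_new;
    for (int t = 0; t < n; ++t) {
      u[t] += y[i] * dai * K[(size_t)i * n + t] +
              y[j] * daj * K[(size_t)j * n + t];
    }
  }
  // bias: average KKT condition over free SVs, else violating-pair midpoint
  double b = 0.0;
  int n_free = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-12 && alpha[t] < C - 1e-12) {
      b += y[t] - u[t];
      ++n_free;
    }
  }
  if (n_free > 0) {
    b /= n_free;
  } else {
    b = (m_up + m_low) / 2.0;
  }
  NumericVector w(d);
  for (int t = 0; t < n; ++t) {
    if (alpha[t] != 0.0) {
      double c = alpha[t] * y[t];
      for (int k = 0; k < d; ++k) w[k] += c * X(t, k);
    }
  }
  return List::create(_["w"] = w, _["b"] = b,
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["iterations"] = iter);
}
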