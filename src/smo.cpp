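#include <Rcpp.h>
using namespace Rcpp;

// Sequential minimal optimization for the soft-margin SVM dual:
// minimize (1/2) a'Qa - 1'a, Q_ij = y_i y_j K_ij,
// s.t. sum_i a_i y_i = 0, 0 <= a_i <= C.
// Maximal-violating-pair working-set selection; stops when the KKT
// violation m(a) - M(a) drops below tol. Returns alpha and the gradient
// G = Qa - 1 (bias and objective are derived from G by the caller).
// [[Rcpp::export]]
List smo_cpp(NumericMatrix K, NumericVector y, double C, double tol,
             int max_iter, NumericVector alpha0) {
  const int n = y.size();
  std::vector<double> alpha(n), G(n);
  bool warm = alpha0.size() == n;
  for (int i = 0; i < n; ++i) alpha[i] = warm ? alpha0[i] : 0.0;
  if (warm) {
    std::vector<double> ay(n);
    for (int j = 0; j < n; ++j) ay[j] = alpha[j] * y[j];
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < n; ++j) s += K(i, j) * ay[j];
      G[i] = y[i] * s - 1.0;
    }
  } else {
    for (int i = 0; i < n; ++i) G[i] = -1.0;
  }
  const double eps = 1e-12;
  int it = 0;
  bool converged = false;
  while (true) {
    // i: argmax over I_up of -y G; j: argmin over I_low
    double gmax = -1e300, gmin = 1e300;
    int ii = -1, jj = -1;
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool up = (y[t] > 0 && alpha[t] < C - eps) ||
                (y[t] < 0 && alpha[t] > eps);
      bool lo = (y[t] < 0 && alpha[t] < C - eps) ||
                (y[t] > 0 && alpha[t] > eps);
      if (up && v > gmax) { gmax = v; ii = t; }
      if (lo && v < gmin) { gmin = v; jj = t; }
    }
    if (ii < 0 || jj < 0 || gmax - gmin < tol) { converged = true; break; }
    if (it >= max_iter) break;
    ++it;
    const int i = ii, j = jj;
    double Ei = y[i] * G[i], Ej = y[j] * G[j];
    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta < 1e-12) eta = 1e-12;
    double ai_old = alpha[i], aj_old = alpha[j];
    double aj = aj_old + y[j] * (Ei - Ej) / eta;
    double L, H;
    if (y[i] != y[j]) {
      L = std::max(0.0, aj_old - ai_old);
      H = std::min(C, C + aj_old - ai_old);
    } else {
      L = std::max(0.0, ai_old + aj_old - C);
      H = std::min(C, ai_old + aj_old);
    }
    if (aj > H) aj = H;
    if (aj < L) aj = L;
    double ai = ai_old + y[i] * y[j] * (aj_old - aj);
    double dI = ai - ai_old, dJ = aj - aj_old;
    if (std::fabs(dI) < 1e-15 && std::fabs(dJ) < 1e-15) {
      converged = true;
      break;
    }
    alpha[i] = ai;
    alpha[j] = aj;
    double ci = y[i] * dI, cj = y[j] * dJ;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (K(t, i) * ci + K(t, j) * cj);
  }
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["G"] = NumericVector(G.begin(), G.end()),
                      _["iterations"] = it, _["converged"] = converged);
}
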