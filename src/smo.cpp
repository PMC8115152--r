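#include <Rcpp.h>
using namespace Rcpp;

// Maximal-violating-pair SMO for the epsilon-SVR dual in net coefficients
// beta_i = a_i - a_i*:
//   maximize W(beta) = y'beta - eps * sum|beta| - 1/2 beta' K beta
//   s.t. sum(beta) = 0, -C <= beta_i <= C.
// Each iteration selects the feasible ascent pair (i up, j down) with the
// largest joint KKT violation and solves the two-variable subproblem
// exactly; the subproblem is piecewise quadratic in t = beta_i because of
// the |beta| kinks at 0, so every region optimum and breakpoint is tried.
// [[Rcpp::export(name = ".smo_solve_cpp")]]
List smo_solve_cpp(NumericMatrix K, NumericVector y, double C,
                   double epsilon, double tol, int max_iter) {
  int n = y.size();
  NumericVector beta(n);
  NumericVector g = clone(y);  // plain gradient y - K beta
  int iter = 0;
  bool converged = false;

  while (iter < max_iter) {
    ++iter;
    // directional derivatives with the kink
    double best_up = R_NegInf, best_dn = R_NegInf, second_dn = R_NegInf;
    int i = -1, j = -1, j2 = -1;
    for (int k = 0; k < n; ++k) {
      double du = (beta[k] >= 0) ? g[k] - epsilon : g[k] + epsilon;
      double dd = (beta[k] <= 0) ? -g[k] - epsilon : -g[k] + epsilon;
      if (beta[k] >= C) du = R_NegInf;
      if (beta[k] <= -C) dd = R_NegInf;
      if (du > best_up) { best_up = du; i = k; }
      if (dd > best_dn) { second_dn = best_dn; j2 = j; best_dn = dd; j = k; }
      else if (dd > second_dn) { second_dn = dd; j2 = k; }
    }
    if (i < 0 || j < 0) { converged = true; break; }
    if (i == j) { j = j2; best_dn = second_dn; }
    if (j < 0 || best_up + best_dn <= tol) { converged = true; break; }

    double s = beta[i] + beta[j];
    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    double t_old = beta[i];
    double lo = std::max(-C, s - C), hi = std::min(C, s + C);
    double slope = g[i] - g[j];

    // candidate t values: bounds, kink breakpoints, per-region optima
    double cand[8];
    int nc = 0;
    cand[nc++] = lo;
    cand[nc++] = hi;
    if (0.0 > lo && 0.0 < hi) cand[nc++] = 0.0;
    if (s > lo && s < hi) cand[nc++] = s;
    if (eta > 1e-12) {
      for (int st = -1; st <= 1; st += 2) {
        for (int su = -1; su <= 1; su += 2) {
          double t = t_old + (slope - epsilon * st + epsilon * su) / eta;
          bool ok_t = (st > 0) ? (t >= 0.0) : (t <= 0.0);
          bool ok_u = (su > 0) ? (s - t >= 0.0) : (s - t <= 0.0);
          if (t >= lo && t <= hi && ok_t && ok_u) cand[nc++] = t;
        }
      }
    }
    double base_kink = epsilon * std::abs(t_old) +
                       epsilon * std::abs(s - t_old);
    double best_w = R_NegInf, t_new = t_old;
    for (int c = 0; c < nc; ++c) {
      double t = cand[c];
      double dt = t - t_old;
      double w = slope * dt - 0.5 * eta * dt * dt -
                 epsilon * std::abs(t) - epsilon * std::abs(s - t) +
                 base_kink;
      if (w > best_w) { best_w = w; t_new = t; }
    }
    if (std::abs(t_new - t_old) < 1e-14) { converged = true; break; }

    double d = t_new - t_old;
    beta[i] = t_new;
    beta[j] = s - t_new;
    for (int k = 0; k < n; ++k) g[k] -= (K(k, i) - K(k, j)) * d;
  }

  return List::create(_["beta"] = beta, _["iterations"] = iter,
                      _["converged"] = converged);
}
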