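#include <Rcpp.h>
using namespace Rcpp;

// Block coordinate descent for the graphical lasso with unpenalised
// diagonal: maximises log det(Theta) - tr(S Theta) - lambda * sum_{i!=j}
// |Theta_ij|. W is the working covariance estimate (diag fixed at diag(S)),
// B holds the per-column lasso coefficients; both may be warm-started.
// [[Rcpp::export]]
List glasso_cd(NumericMatrix S, double lambda, int max_iterations,
               double tolerance, NumericMatrix W_init,
               NumericMatrix B_init) {
  const int p = S.nrow();
  NumericMatrix W(clone(W_init));
  NumericMatrix B(clone(B_init));

  double off_sum = 0.0;
  int off_n = 0;
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j) {
      off_sum += std::fabs(S(i, j));
      ++off_n;
    }
  double scale_ref = off_n > 0 ? off_sum / off_n : 0.0;
  if (scale_ref < 1e-12) scale_ref = 1e-12;
  const double cd_tol = 1e-10 * std::max(scale_ref, 1.0);

  std::vector<int> idx(p - 1);
  std::vector<double> beta(p - 1), s12(p - 1);
  std::vector<double> W11((p - 1) * (p - 1));

  int it = 0;
  bool converged = false;
  while (it < max_iterations) {
    ++it;
    double sweep_change = 0.0;
    for (int j = 0; j < p; ++j) {
      int m = 0;
      for (int i = 0; i < p; ++i)
        if (i != j) idx[m++] = i;
      for (int a = 0; a < p - 1; ++a) {
        s12[a] = S(idx[a], j);
        beta[a] = B(idx[a], j);
        for (int b = 0; b < p - 1; ++b)
          W11[a * (p - 1) + b] = W(idx[a], idx[b]);
      }
      for (int cd = 0; cd < 1000; ++cd) {
        double delta = 0.0;
        for (int a = 0; a < p - 1; ++a) {
          double dot = 0.0;
          for (int b = 0; b < p - 1; ++b)
            dot += W11[a * (p - 1) + b] * beta[b];
          double r = s12[a] - dot + W11[a * (p - 1) + a] * beta[a];
          double bnew = 0.0;
          double ar = std::fabs(r);
          if (ar > lambda)
            bnew = (r > 0 ? ar - lambda : lambda - ar) /
                   W11[a * (p - 1) + a];
          double d = std::fabs(bnew - beta[a]);
          if (d > delta) delta = d;
          beta[a] = bnew;
        }
        if (delta < cd_tol) break;
      }
      for (int a = 0; a < p - 1; ++a) {
        B(idx[a], j) = beta[a];
        double w12 = 0.0;
        for (int b = 0; b < p - 1; ++b)
          w12 += W11[a * (p - 1) + b] * beta[b];
        double ch = std::fabs(w12 - W(idx[a], j));
        sweep_change += 2.0 * ch;
        W(idx[a], j) = w12;
        W(j, idx[a]) = w12;
      }
    }
    if (sweep_change / (p * p) < tolerance * scale_ref) {
      converged = true;
      break;
    }
  }

  NumericMatrix Theta(p, p);
  for (int j = 0; j < p; ++j) {
    double dot = 0.0;
    for (int i = 0; i < p; ++i)
      if (i != j) dot += W(i, j) * B(i, j);
    double theta_jj = 1.0 / (W(j, j) - dot);
    Theta(j, j) = theta_jj;
    for (int i = 0; i < p; ++i)
      if (i != j) Theta(i, j) = -B(i, j) * theta_jj;
  }
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j) {
      double v = 0.5 * (Theta(i, j) + Theta(j, i));
      Theta(i, j) = v;
      Theta(j, i) = v;
    }

  return List::create(_["precision"] = Theta, _["covariance"] = W,
                      _["beta"] = B, _["iterations"] = it,
                      _["converged"] = converged);
}
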