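#include <Rcpp.h>
using namespace Rcpp;

// Graphical lasso: block coordinate descent on the covariance estimate W
// (Friedman et al. style). Each column update solves a lasso problem with
// Gram matrix W11 and response s12 by cyclic coordinate descent. Returns the
// estimated covariance W, precision Theta, and the adjacency of nonzero
// off-diagonal precision entries.
// [[Rcpp::export]]
List glasso_cpp(NumericMatrix S, double rho, double tol = 1e-4,
                int maxit = 100, int cd_maxit = 200) {
  int p = S.nrow();
  NumericMatrix W(clone(S));
  for (int j = 0; j < p; ++j) W(j, j) = S(j, j) + rho;
  NumericMatrix B(p, p);  // B(k, j): lasso coefficients for column j (k != j)

  double offsum = 0.0;
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (i != j) offsum += std::fabs(S(i, j));
  double thr = tol * (offsum / std::max(1, p * (p - 1)));
  if (thr <= 0) thr = tol * 1e-4;

  for (int it = 0; it < maxit; ++it) {
    double max_change = 0.0;
    for (int j = 0; j < p; ++j) {
      // coordinate descent for beta: minimize
      //   .5 b' W11 b - s12' b + rho |b|_1
      for (int cd = 0; cd < cd_maxit; ++cd) {
        double cd_change = 0.0;
        for (int k = 0; k < p; ++k) {
          if (k == j) continue;
          double r = S(k, j);
          for (int l = 0; l < p; ++l) {
            if (l == j || l == k) continue;
            r -= W(k, l) * B(l, j);
          }
          double bnew = 0.0;
          double denom = W(k, k);
          if (std::fabs(r) > rho)
            bnew = (r > 0 ? r - rho : r + rho) / denom;
          double d = std::fabs(bnew - B(k, j));
          if (d > cd_change) cd_change = d;
          B(k, j) = bnew;
        }
        if (cd_change < thr) break;
      }
      for (int k = 0; k < p; ++k) {
        if (k == j) continue;
        double w = 0.0;
        for (int l = 0; l < p; ++l) {
          if (l == j) continue;
          w += W(k, l) * B(l, j);
        }
        double d = std::fabs(w - W(k, j));
        if (d > max_change) max_change = d;
        W(k, j) = w;
        W(j, k) = w;
      }
    }
    if (max_change < thr) break;
  }

  NumericMatrix Theta(p, p);
  for (int j = 0; j < p; ++j) {
    double dot = 0.0;
    for (int k = 0; k < p; ++k)
      if (k != j) dot += W(k, j) * B(k, j);
    double t22 = 1.0 / (W(j, j) - dot);
    Theta(j, j) = t22;
    for (int k = 0; k < p; ++k)
      if (k != j) Theta(k, j) = -B(k, j) * t22;
  }
  // symmetrize (numerically) and build adjacency
  LogicalMatrix adj(p, p);
  for (int i = 0; i < p; ++i) {
    for (int j = i + 1; j < p; ++j) {
      double t = 0.5 * (Theta(i, j) + Theta(j, i));
      Theta(i, j) = t;
      Theta(j, i) = t;
      bool nz = std::fabs(B(i, j)) > 1e-10 || std::fabs(B(j, i)) > 1e-10;
      adj(i, j) = nz;
      adj(j, i) = nz;
    }
  }
  return List::create(_["w"] = W, _["theta"] = Theta, _["adj"] = adj);
}
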