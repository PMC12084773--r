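#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double soft(double z, double lam) {
  if (z > lam) return z - lam;
  if (z < -lam) return z + lam;
  return 0.0;
}

// Cyclic coordinate descent for
//   min_beta 1/2 beta' G beta - c' beta + lam * ||beta||_1
// which is the Gram-matrix form of (1/2n)||y - X beta||^2 + lam ||beta||_1
// with G = X'X/n, c = X'y/n. Convergence: max absolute coefficient change.
// [[Rcpp::export]]
List cd_lasso_gram_cpp(NumericMatrix G, NumericVector c, double lam,
                       NumericVector beta0, double tol, int maxit) {
  int p = c.size();
  NumericVector beta = clone(beta0);
  int it = 0;
  double delta = R_PosInf;
  for (it = 0; it < maxit; ++it) {
    delta = 0.0;
    for (int j = 0; j < p; ++j) {
      double gj = G(j, j);
      if (gj <= 0.0) { beta[j] = 0.0; continue; }
      double r = c[j];
      for (int k = 0; k < p; ++k) if (k != j) r -= G(j, k) * beta[k];
      double bnew = soft(r, lam) / gj;
      double d = std::fabs(bnew - beta[j]);
      if (d > delta) delta = d;
      beta[j] = bnew;
    }
    if (delta < tol) break;
  }
  return List::create(_["beta"] = beta,
                      _["iterations"] = it + 1,
                      _["converged"] = (delta < tol));
}

// Full lasso path over a decreasing lambda grid with warm starts.
// Returns p x nlambda coefficient matrix.
// [[Rcpp::export]]
NumericMatrix cd_lasso_path_cpp(NumericMatrix G, NumericVector c,
                                NumericVector lambdas, double tol, int maxit) {
  int p = c.size(), nl = lambdas.size();
  NumericMatrix B(p, nl);
  NumericVector beta(p);
  for (int l = 0; l < nl; ++l) {
    double lam = lambdas[l];
    for (int it = 0; it < maxit; ++it) {
      double delta = 0.0;
      for (int j = 0; j < p; ++j) {
        double gj = G(j, j);
        if (gj <= 0.0) { beta[j] = 0.0; continue; }
        double r = c[j];
        for (int k = 0; k < p; ++k) if (k != j) r -= G(j, k) * beta[k];
        double bnew = soft(r, lam) / gj;
        double d = std::fabs(bnew - beta[j]);
        if (d > delta) delta = d;
        beta[j] = bnew;
      }
      if (delta < tol) break;
    }
    for (int j = 0; j < p; ++j) B(j, l) = beta[j];
  }
  return B;
}

// Graphical lasso (block coordinate descent on the covariance estimate W),
// L1 penalty on off-diagonal precision entries only. Standard algorithm:
// cycle over columns, solve the column lasso subproblem
//   min_b 1/2 b' W11 b - s12' b + rho ||b||_1
// update w12 = W11 b; on convergence recover Theta from the final B.
// [[Rcpp::export]]
List glasso_cpp(NumericMatrix S, double rho, NumericMatrix W0, NumericMatrix B0,
                double tol, int maxit, double inner_tol, int inner_maxit) {
  int p = S.nrow();
  NumericMatrix W = clone(W0);
  NumericMatrix B = clone(B0);  // column j holds beta for response j
  int it = 0;
  double delta = R_PosInf;

  std::vector<int> idx(p - 1);
  for (it = 0; it < maxit; ++it) {
    delta = 0.0;
    for (int j = 0; j < p; ++j) {
      int m = 0;
      for (int k = 0; k < p; ++k) if (k != j) idx[m++] = k;
      // inner lasso by coordinate descent, warm-started at B(, j)
      for (int in_it = 0; in_it < inner_maxit; ++in_it) {
        double din = 0.0;
        for (int a = 0; a < p - 1; ++a) {
          int ka = idx[a];
          double w_aa = W(ka, ka);
          if (w_aa <= 0.0) { B(ka, j) = 0.0; continue; }
          double r = S(ka, j);
          for (int b = 0; b < p - 1; ++b) {
            int kb = idx[b];
            if (kb != ka) r -= W(ka, kb) * B(kb, j);
          }
          double bnew = soft(r, rho) / w_aa;
          double d = std::fabs(bnew - B(ka, j));
          if (d > din) din = d;
          B(ka, j) = bnew;
        }
        if (din < inner_tol) break;
      }
      // w12 = W11 beta
      for (int a = 0; a < p - 1; ++a) {
        int ka = idx[a];
        double w = 0.0;
        for (int b = 0; b < p - 1; ++b) w += W(ka, idx[b]) * B(idx[b], j);
        double d = std::fabs(w - W(ka, j));
        if (d > delta) delta = d;
        W(ka, j) = w;
        W(j, ka) = w;
      }
    }
    if (delta < tol) break;
  }

  // Recover Theta: theta_jj = 1/(w_jj - w12' beta_j), theta_12 = -beta_j*theta_jj
  NumericMatrix Theta(p, p);
  for (int j = 0; j < p; ++j) {
    double q = W(j, j);
    for (int k = 0; k < p; ++k) if (k != j) q -= W(k, j) * B(k, j);
    double tjj = 1.0 / q;
    Theta(j, j) = tjj;
    for (int k = 0; k < p; ++k) if (k != j) Theta(k, j) = -B(k, j) * tjj;
  }
  // symmetrize (numerically; exact zeros stay exact zeros)
  for (int j = 0; j < p; ++j)
    for (int k = j + 1; k < p; ++k) {
      if (Theta(j, k) == 0.0 || Theta(k, j) == 0.0) {
        Theta(j, k) = 0.0; Theta(k, j) = 0.0;
      } else {
        double v = 0.5 * (Theta(j, k) + Theta(k, j));
        Theta(j, k) = v; Theta(k, j) = v;
      }
    }
  return List::create(_["W"] = W, _["Theta"] = Theta, _["B"] = B,
                      _["iterations"] = it + 1,
                      _["converged"] = (delta < tol));
}

// Full node-wise lasso CLPN fit with per-response k-fold CV.
// Zf, Zt: standardized n x p wave matrices; fold_id in 1..k.
// For each response j: lambda path log-spaced from max|Zf'y|/n down to
// ratio times it; per fold, coordinate-descent path on the training Gram
// with warm starts; validation MSE via quadratic forms; the CV-minimum
// lambda is refit on the full sample.
// [[Rcpp::export]]
List clpn_cv_cpp(NumericMatrix Zf, NumericMatrix Zt, IntegerVector fold_id,
                 int n_lambda, double ratio, double tol, int maxit,
                 double cv_tol) {
  int n = Zf.nrow(), p = Zf.ncol();
  int k = 0;
  for (int i = 0; i < n; ++i) if (fold_id[i] > k) k = fold_id[i];

  // full-sample Gram and cross-products
  std::vector<double> G(p * p, 0.0), C(p * p, 0.0);
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < p; ++a) {
      double za = Zf(i, a);
      for (int b = a; b < p; ++b) G[a * p + b] += za * Zf(i, b);
      for (int b = 0; b < p; ++b) C[b * p + a] += za * Zt(i, b); // C[j][a] = sum zf_a * zt_j
    }
  for (int a = 0; a < p; ++a)
    for (int b = 0; b < a; ++b) G[a * p + b] = G[b * p + a];
  for (auto &v : G) v /= n;
  for (auto &v : C) v /= n;

  // per-fold training/validation Grams and cross-products
  std::vector<int> nval(k, 0);
  std::vector<double> Gv(k * p * p, 0.0), Cv(k * p * p, 0.0), yss(k * p, 0.0);
  for (int i = 0; i < n; ++i) {
    int f = fold_id[i] - 1;
    nval[f]++;
    double *gv = &Gv[f * p * p], *cv = &Cv[f * p * p];
    for (int a = 0; a < p; ++a) {
      double za = Zf(i, a);
      for (int b = a; b < p; ++b) gv[a * p + b] += za * Zf(i, b);
      for (int b = 0; b < p; ++b) cv[b * p + a] += za * Zt(i, b);
    }
    for (int j = 0; j < p; ++j) yss[f * p + j] += Zt(i, j) * Zt(i, j);
  }
  for (int f = 0; f < k; ++f) {
    double *gv = &Gv[f * p * p];
    for (int a = 0; a < p; ++a)
      for (int b = 0; b < a; ++b) gv[a * p + b] = gv[b * p + a];
  }

  NumericMatrix B_hat(p, p);
  NumericVector lambda_used(p);
  std::vector<double> Gtr(p * p), ctr(p), beta(p), lam(n_lambda),
      mse(n_lambda), bwork(p);

  for (int j = 0; j < p; ++j) {
    // lambda path from the full-sample cross-products
    double lmax = 0.0;
    for (int a = 0; a < p; ++a)
      if (std::fabs(C[j * p + a]) > lmax) lmax = std::fabs(C[j * p + a]);
    if (lmax <= 0) lmax = 1e-3;
    double llo = std::log(lmax * ratio), lhi = std::log(lmax);
    for (int l = 0; l < n_lambda; ++l)
      lam[l] = std::exp(lhi + (llo - lhi) * l / (n_lambda - 1));
    std::fill(mse.begin(), mse.end(), 0.0);

    for (int f = 0; f < k; ++f) {
      int ntr = n - nval[f];
      double *gv = &Gv[f * p * p], *cv = &Cv[f * p * p];
      for (int a = 0; a < p * p; ++a) Gtr[a] = (G[a] * n - gv[a]) / ntr;
      for (int a = 0; a < p; ++a)
        ctr[a] = (C[j * p + a] * n - cv[j * p + a]) / ntr;
      std::fill(beta.begin(), beta.end(), 0.0);
      double yms = yss[f * p + j] / nval[f];
      for (int l = 0; l < n_lambda; ++l) {
        double lm = lam[l];
        for (int it = 0; it < maxit; ++it) {
          double delta = 0.0;
          for (int a = 0; a < p; ++a) {
            double g = Gtr[a * p + a];
            if (g <= 0) { beta[a] = 0; continue; }
            double r = ctr[a];
            for (int b = 0; b < p; ++b) if (b != a) r -= Gtr[a * p + b] * beta[b];
            double z = (std::fabs(r) > lm) ? (r > 0 ? r - lm : r + lm) / g : 0.0;
            double d = std::fabs(z - beta[a]);
            if (d > delta) delta = d;
            beta[a] = z;
          }
          if (delta < cv_tol) break;
        }
        // validation MSE: E[y^2] - 2 c_val'b + b' G_val b  (per-cell scale)
        double lin = 0.0, quad = 0.0;
        for (int a = 0; a < p; ++a) {
          if (beta[a] == 0.0) { bwork[a] = 0.0; continue; }
          lin += cv[j * p + a] * beta[a];
          double s = 0.0;
          for (int b = 0; b < p; ++b) if (beta[b] != 0.0) s += gv[a * p + b] * beta[b];
          bwork[a] = s;
          quad += beta[a] * s;
        }
        mse[l] += yms - 2.0 * lin / nval[f] + quad / nval[f];
      }
    }
    int best = 0;
    for (int l = 1; l < n_lambda; ++l) if (mse[l] < mse[best]) best = l;
    lambda_used[j] = lam[best];

    // refit on the full sample at the selected lambda (warm from zero,
    // descending the path down to it for stability)
    std::fill(beta.begin(), beta.end(), 0.0);
    for (int l = 0; l <= best; ++l) {
      double lm = lam[l];
      for (int it = 0; it < maxit; ++it) {
        double delta = 0.0;
        for (int a = 0; a < p; ++a) {
          double g = G[a * p + a];
          if (g <= 0) { beta[a] = 0; continue; }
          double r = C[j * p + a];
          for (int b = 0; b < p; ++b) if (b != a) r -= G[a * p + b] * beta[b];
          double z = (std::fabs(r) > lm) ? (r > 0 ? r - lm : r + lm) / g : 0.0;
          double d = std::fabs(z - beta[a]);
          if (d > delta) delta = d;
          beta[a] = z;
        }
        if (delta < tol) break;
      }
    }
    for (int a = 0; a < p; ++a) B_hat(a, j) = beta[a];
  }
  return List::create(_["B_hat"] = B_hat, _["lambda_used"] = lambda_used);
}
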