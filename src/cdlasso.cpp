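#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Cyclic coordinate descent for the lasso objective
//   (1/(2n)) * sum_i (yc_i - sum_j X(i,j) b_j)^2 + lambda * sum_j pf_j |b_j|
// on a column-centered design (the intercept is handled by the caller).
// colvar_j = <x_j, x_j>/n lets the same routine serve standardized
// (colvar = 1) and raw-scale fits; columns with colvar_j == 0 are frozen
// at zero. Solutions are computed along a decreasing lambda sequence with
// warm starts; within each lambda an active-set strategy iterates over the
// currently nonzero coordinates until convergence, then verifies a full
// sweep over all coordinates.

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// one coordinate update; returns |delta|
static inline double update_coord(const double* xj, const int n,
                                  const double vj, const double pen,
                                  double* r, double& bj) {
  double dot = 0.0;
  for (int i = 0; i < n; ++i) dot += xj[i] * r[i];
  const double z = bj * vj + dot / n;
  const double bnew = soft(z, pen) / vj;
  const double del = bnew - bj;
  if (del != 0.0) {
    for (int i = 0; i < n; ++i) r[i] -= xj[i] * del;
    bj = bnew;
  }
  return std::fabs(del);
}

// path solve on prepared (centered) data held in column-major `Xp`
static void fit_path_core(const double* Xp, const double* yc,
                          const int n, const int p,
                          const double* lambda, const int nl,
                          const double* pf, const double* colvar,
                          const double tol, const int max_iter,
                          double* beta_out, int* conv_out) {
  std::vector<double> b(p, 0.0);
  std::vector<double> r(yc, yc + n);
  std::vector<int> active;
  active.reserve(p);

  for (int l = 0; l < nl; ++l) {
    const double lam = lambda[l];
    bool ok = false;
    for (int outer = 0; outer < max_iter; ++outer) {
      // full sweep over all coordinates
      double maxdel = 0.0;
      for (int j = 0; j < p; ++j) {
        if (colvar[j] <= 0.0) { b[j] = 0.0; continue; }
        const double d = update_coord(Xp + (size_t)j * n, n, colvar[j],
                                      lam * pf[j], r.data(), b[j]);
        if (d > maxdel) maxdel = d;
      }
      if (maxdel < tol) { ok = true; break; }
      // inner iterations restricted to the active set
      active.clear();
      for (int j = 0; j < p; ++j)
        if (b[j] != 0.0 && colvar[j] > 0.0) active.push_back(j);
      for (int inner = 0; inner < max_iter; ++inner) {
        double mdel = 0.0;
        for (size_t a = 0; a < active.size(); ++a) {
          const int j = active[a];
          const double d = update_coord(Xp + (size_t)j * n, n, colvar[j],
                                        lam * pf[j], r.data(), b[j]);
          if (d > mdel) mdel = d;
        }
        if (mdel < tol) break;
      }
    }
    for (int j = 0; j < p; ++j) beta_out[(size_t)l * p + j] = b[j];
    conv_out[l] = ok ? 1 : 0;
  }
}

// maximal penalty: the same sequential accumulation as update_coord, so
// that soft-thresholding at exactly lambda_max yields an all-zero solution
// [[Rcpp::export(name = ".cd_lambda_max")]]
double cd_lambda_max(const NumericMatrix& X,
                     const NumericVector& yc,
                     const NumericVector& pf,
                     const NumericVector& colvar) {
  const int n = X.nrow();
  const int p = X.ncol();
  const double* Xp = REAL(X);
  double lmax = 0.0;
  for (int j = 0; j < p; ++j) {
    if (pf[j] <= 0.0 || colvar[j] <= 0.0) continue;
    const double* xj = Xp + (size_t)j * n;
    double dot = 0.0;
    for (int i = 0; i < n; ++i) dot += xj[i] * yc[i];
    const double g = std::fabs(dot / n) / pf[j];
    if (g > lmax) lmax = g;
  }
  return lmax;
}

// [[Rcpp::export(name = ".cd_lasso_path")]]
List cd_lasso_path(const NumericMatrix& X,
                   const NumericVector& yc,
                   const NumericVector& lambda,
                   const NumericVector& pf,
                   const NumericVector& colvar,
                   const double tol,
                   const int max_iter) {
  const int n = X.nrow();
  const int p = X.ncol();
  const int nl = lambda.size();
  NumericMatrix beta(p, nl);
  IntegerVector conv(nl);
  fit_path_core(REAL(X), REAL(yc), n, p, REAL(lambda), nl, REAL(pf),
                REAL(colvar), tol, max_iter, REAL(beta), INTEGER(conv));
  return List::create(_["beta"] = beta, _["converged"] = conv);
}

// K-fold cross-validation driver: per fold, center/standardize the
// training block, path-solve with warm starts, and score the held-out
// rows. foldid is 1-based; folds whose training outcome is constant
// degenerate to intercept-only predictions (flagged in `degenerate`).
// [[Rcpp::export(name = ".cd_lasso_cv")]]
List cd_lasso_cv(const NumericMatrix& X,
                 const NumericVector& y,
                 const IntegerVector& foldid,
                 const int nfold,
                 const NumericVector& lambda,
                 const NumericVector& pf,
                 const bool standardize,
                 const double tol,
                 const int max_iter) {
  const int n = X.nrow();
  const int p = X.ncol();
  const int nl = lambda.size();
  NumericMatrix mse(nl, nfold);
  LogicalVector degen(nfold);
  const double* Xall = REAL(X);

  std::vector<double> Xtr((size_t)n * p), yc(n), m(p), s(p), colvar(p);
  std::vector<double> beta((size_t)p * nl);
  std::vector<int> conv(nl), rows(n);

  for (int f = 1; f <= nfold; ++f) {
    int ntr = 0, nva = 0;
    std::vector<int> va(n);
    for (int i = 0; i < n; ++i) {
      if (foldid[i] == f) va[nva++] = i; else rows[ntr++] = i;
    }
    if (nva == 0) { for (int l = 0; l < nl; ++l) mse(l, f - 1) = NA_REAL; continue; }

    double ymean = 0.0;
    for (int i = 0; i < ntr; ++i) ymean += y[rows[i]];
    ymean /= ntr;
    double yvar = 0.0;
    for (int i = 0; i < ntr; ++i) {
      yc[i] = y[rows[i]] - ymean;
      yvar += yc[i] * yc[i];
    }
    if (yvar == 0.0) {
      degen[f - 1] = true;
      for (int l = 0; l < nl; ++l) {
        double acc = 0.0;
        for (int i = 0; i < nva; ++i) {
          const double e = y[va[i]] - ymean;
          acc += e * e;
        }
        mse(l, f - 1) = acc / nva;
      }
      continue;
    }

    for (int j = 0; j < p; ++j) {
      const double* xj = Xall + (size_t)j * n;
      double mj = 0.0;
      for (int i = 0; i < ntr; ++i) mj += xj[rows[i]];
      mj /= ntr;
      double vj = 0.0;
      double* tj = Xtr.data() + (size_t)j * ntr;
      for (int i = 0; i < ntr; ++i) {
        tj[i] = xj[rows[i]] - mj;
        vj += tj[i] * tj[i];
      }
      vj /= ntr;
      m[j] = mj;
      if (standardize) {
        const double sj = std::sqrt(vj);
        if (sj > 0.0) {
          for (int i = 0; i < ntr; ++i) tj[i] /= sj;
          s[j] = sj;
          colvar[j] = 1.0;
        } else {
          s[j] = 1.0;
          colvar[j] = 0.0;
        }
      } else {
        s[j] = 1.0;
        colvar[j] = vj;
      }
    }

    fit_path_core(Xtr.data(), yc.data(), ntr, p, REAL(lambda), nl,
                  REAL(pf), colvar.data(), tol, max_iter,
                  beta.data(), conv.data());

    for (int l = 0; l < nl; ++l) {
      const double* bl = beta.data() + (size_t)l * p;
      double acc = 0.0;
      for (int i = 0; i < nva; ++i) {
        double pred = ymean;
        const int row = va[i];
        for (int j = 0; j < p; ++j) {
          if (bl[j] != 0.0)
            pred += bl[j] * (Xall[(size_t)j * n + row] - m[j]) / s[j];
        }
        const double e = y[row] - pred;
        acc += e * e;
      }
      mse(l, f - 1) = acc / nva;
    }
  }
  return List::create(_["mse"] = mse, _["degenerate"] = degen);
}
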