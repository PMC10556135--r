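// Core numerical kernels for the GPCM-DIF penalized joint likelihood.
// Category probabilities use a log-sum-exp guard throughout.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Penalized smooth-block negative objective and gradient in
// (theta, beta, ln alpha) plus any sign-fixed active DIF offsets.
//
// par layout: [theta (N, if free_theta)] [beta, concatenated over the
// itemset] [ln alpha (K, if free_alpha)] [active delta coordinates,
// item-major / covariate-minor].
// X holds responses with NA for missing; items0 are 0-based column
// indices of the itemset; nb the per-item threshold counts.  kappa is
// the N x m_f membership matrix; delta_fixed the K x m_f inactive
// offsets; delta_free flags (K x m_f) mark coordinates taken from `par`,
// whose sign is fixed by delta_sign, making the lasso term linear here
// (the caller constrains the sign with box bounds).
// [[Rcpp::export]]
List gdif_smooth_cpp(NumericVector par, IntegerMatrix X, IntegerVector items0,
                     IntegerVector nb, NumericMatrix kappa,
                     NumericMatrix delta_fixed, IntegerMatrix delta_free,
                     NumericMatrix delta_sign,
                     bool free_theta, NumericVector theta_fixed,
                     bool free_alpha, double lambda_theta,
                     double lambda_alpha, double lambda_delta) {
  const int N = X.nrow();
  const int K = items0.size();
  const int mf = kappa.ncol();
  const int n_theta = free_theta ? N : 0;
  int n_beta = 0;
  for (int k = 0; k < K; k++) n_beta += nb[k];
  const int n_alpha = free_alpha ? K : 0;

  // map active delta coordinates to par indices (item-major order)
  std::vector<int> didx(K * mf, -1);
  int nd = 0;
  for (int k = 0; k < K; k++)
    for (int f = 0; f < mf; f++)
      if (delta_free(k, f)) didx[k * mf + f] = n_theta + n_beta + n_alpha + nd++;

  NumericVector grad(par.size());
  double f = 0.0;

  std::vector<double> theta(N);
  for (int n = 0; n < N; n++)
    theta[n] = free_theta ? par[n] : theta_fixed[n];

  std::vector<double> cb(32), pr(32), cum(32), dk(mf > 0 ? mf : 1);
  int boff = 0;
  for (int k = 0; k < K; k++) {
    const int mi = nb[k];
    const double *bk = &par[n_theta + boff];
    const double lna = free_alpha ? par[n_theta + n_beta + k] : 0.0;
    const double a = std::exp(lna);
    const int col = items0[k];
    for (int f2 = 0; f2 < mf; f2++)
      dk[f2] = delta_free(k, f2) ? par[didx[k * mf + f2]] : delta_fixed(k, f2);
    cb[0] = 0.0;
    for (int j = 1; j <= mi; j++) cb[j] = cb[j - 1] + bk[j - 1];
    double glna = 0.0;
    for (int n = 0; n < N; n++) {
      const int x = X(n, col);
      if (x == NA_INTEGER) continue;
      double shift = 0.0;
      for (int f2 = 0; f2 < mf; f2++) shift += dk[f2] * kappa(n, f2);
      const double u = theta[n] + shift;
      double mx = 0.0;  // cum[0] = 0
      for (int c = 0; c <= mi; c++) {
        cum[c] = a * (c * u - cb[c]);
        if (cum[c] > mx) mx = cum[c];
      }
      double Z = 0.0;
      for (int c = 0; c <= mi; c++) {
        pr[c] = std::exp(cum[c] - mx);
        Z += pr[c];
      }
      double E = 0.0, Et = 0.0;
      for (int c = 0; c <= mi; c++) {
        pr[c] /= Z;
        E += c * pr[c];
        Et += pr[c] * cum[c];
      }
      f += cum[x] - mx - std::log(Z);
      const double r = a * (x - E);
      if (free_theta) grad[n] += r;
      double Sge = 0.0;
      for (int j = mi; j >= 1; j--) {
        Sge += pr[j];
        const double ind = (x >= j) ? 1.0 : 0.0;
        grad[n_theta + boff + j - 1] -= a * (ind - Sge);
      }
      if (free_alpha) glna += cum[x] - Et;  // = a * (t(x) - E[t])
      for (int f2 = 0; f2 < mf; f2++)
        if (delta_free(k, f2) && kappa(n, f2) != 0.0)
          grad[didx[k * mf + f2]] += r * kappa(n, f2);
    }
    if (free_alpha) grad[n_theta + n_beta + k] = glna;
    boff += mi;
  }

  // penalties; `grad` holds the gradient of the penalized objective
  if (free_theta) {
    for (int n = 0; n < N; n++) {
      f -= lambda_theta * theta[n] * theta[n];
      grad[n] -= 2.0 * lambda_theta * theta[n];
    }
  }
  if (free_alpha) {
    for (int k = 0; k < K; k++) {
      const double lna = par[n_theta + n_beta + k];
      f -= lambda_alpha * lna * lna;
      grad[n_theta + n_beta + k] -= 2.0 * lambda_alpha * lna;
    }
  }
  for (int k = 0; k < K; k++)
    for (int f2 = 0; f2 < mf; f2++)
      if (delta_free(k, f2)) {
        const int i = didx[k * mf + f2];
        f -= lambda_delta * delta_sign(k, f2) * par[i];  // = lambda |delta|
        grad[i] -= lambda_delta * delta_sign(k, f2);
      }

  // optim() minimizes: return the negative objective and gradient
  for (int i = 0; i < grad.size(); i++) grad[i] = -grad[i];
  return List::create(Named("value") = -f, Named("grad") = grad);
}

// Log likelihood of one item over all subjects; x uses NA for missing,
// shift is the per-subject DIF shift for this item.
// [[Rcpp::export]]
double item_loglik_cpp(IntegerVector x, NumericVector theta,
                       NumericVector beta, double alpha,
                       NumericVector shift) {
  const int N = x.size();
  const int mi = beta.size();
  std::vector<double> cb(mi + 1), cum(mi + 1);
  cb[0] = 0.0;
  for (int j = 1; j <= mi; j++) cb[j] = cb[j - 1] + beta[j - 1];
  double ll = 0.0;
  for (int n = 0; n < N; n++) {
    if (x[n] == NA_INTEGER) continue;
    const double u = theta[n] + shift[n];
    double mx = 0.0;
    for (int c = 0; c <= mi; c++) {
      cum[c] = alpha * (c * u - cb[c]);
      if (cum[c] > mx) mx = cum[c];
    }
    double Z = 0.0;
    for (int c = 0; c <= mi; c++) Z += std::exp(cum[c] - mx);
    ll += cum[x[n]] - mx - std::log(Z);
  }
  return ll;
}
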