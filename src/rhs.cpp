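#include <Rcpp.h>
using namespace Rcpp;

// Derivatives of the consumer-resource model with adaptive foraging.
// State layout: y = [p (nP), a (nA), R (nP), alpha (L)].
// Link index vectors lp, la are 1-based (as in the R edge table).
// [[Rcpp::export]]
NumericVector rhs_kernel(NumericVector y,
                         IntegerVector lp, IntegerVector la,
                         int nP, int nA,
                         NumericVector g, NumericVector u, NumericVector w,
                         NumericVector eps, NumericVector mu_p,
                         NumericVector beta, NumericVector phi,
                         NumericVector mu_a, NumericVector G_l,
                         NumericVector tau, NumericVector cc,
                         NumericVector bb, NumericVector ee,
                         double threshold) {
  const int L = lp.size();
  NumericVector dy(y.size());
  std::vector<double> p(nP), R(nP), f(nP), a(nA);
  double up = 0.0;
  for (int i = 0; i < nP; ++i) {
    p[i] = std::max(y[i], 0.0);
    R[i] = std::max(y[nP + nA + i], 0.0);
    f[i] = (p[i] > threshold) ? R[i] / p[i] : 0.0;
    up += u[i] * p[i];
  }
  for (int j = 0; j < nA; ++j) a[j] = std::max(y[nP + j], 0.0);

  std::vector<double> V(L), epsV(L), denom(nA, 0.0), mean_rwd(nA, 0.0),
      rwd(L), alpha(L);
  for (int l = 0; l < L; ++l) {
    const int i = lp[l] - 1, j = la[l] - 1;
    alpha[l] = std::max(y[2 * nP + nA + l], 0.0);
    V[l] = alpha[l] * tau[l] * a[j] * p[i];
    epsV[l] = eps[i] * V[l];
    denom[j] += epsV[l];
    rwd[l] = cc[l] * tau[l] * bb[l] * R[i];
    mean_rwd[j] += alpha[l] * rwd[l];
  }

  std::vector<double> pol(nP, 0.0), extr(nP, 0.0), gain(nA, 0.0);
  for (int l = 0; l < L; ++l) {
    const int i = lp[l] - 1, j = la[l] - 1;
    const double sigma = (denom[j] > 0.0) ? epsV[l] / denom[j] : 0.0;
    pol[i] += ee[l] * sigma * V[l];
    const double Vb = V[l] * bb[l];
    extr[i] += Vb;
    gain[j] += cc[l] * Vb * f[i];
    dy[2 * nP + nA + l] = G_l[l] * alpha[l] * (rwd[l] - mean_rwd[j]);
  }

  for (int i = 0; i < nP; ++i) {
    const double gamma = g[i] * (1.0 - (up - u[i] * p[i]) - w[i] * p[i]);
    dy[i] = gamma * pol[i] - mu_p[i] * p[i];
    dy[nP + nA + i] = beta[i] * p[i] - phi[i] * R[i] - extr[i] * f[i];
  }
  for (int j = 0; j < nA; ++j) dy[nP + j] = gain[j] - mu_a[j] * a[j];
  return dy;
}
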