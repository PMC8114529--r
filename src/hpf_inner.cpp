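#include <Rcpp.h>
using namespace Rcpp;

// Multinomial allocation step of the CAVI sweep for the Gamma-Poisson
// hierarchy. For every nonzero count x_ig the auxiliary allocation
// phi_igk \propto exp(Elog(theta_ik) + Elog(beta_gk)) is formed and the
// expected counts x*phi are accumulated on the cell side (theta) and the
// gene side (beta). The exponentials are taken once per cell/gene row
// rather than per nonzero entry; the geometric-mean expectations involved
// are far from the double range limits, so no log-sum-exp shift is needed.
// Also returns the profile likelihood term
// sum_nz x_ig * log(sum_k exp(Elog theta + Elog beta)), the optimal
// variational value of the allocation entropy plus cross terms.
// [[Rcpp::export]]
List hpf_allocate(IntegerVector ci, IntegerVector gi, NumericVector x,
                  NumericMatrix elogTheta, NumericMatrix elogBeta) {
  const int K = elogTheta.ncol();
  const int n = elogTheta.nrow();
  const int G = elogBeta.nrow();
  const R_xlen_t nnz = x.size();
  NumericMatrix thetaAcc(n, K), betaAcc(G, K);
  std::vector<double> expT(static_cast<size_t>(n) * K);
  std::vector<double> expB(static_cast<size_t>(G) * K);
  for (int k = 0; k < K; ++k) {
    for (int i = 0; i < n; ++i)
      expT[static_cast<size_t>(i) * K + k] = std::exp(elogTheta(i, k));
    for (int g = 0; g < G; ++g)
      expB[static_cast<size_t>(g) * K + k] = std::exp(elogBeta(g, k));
  }
  double lik = 0.0;
  std::vector<double> s(K);
  for (R_xlen_t e = 0; e < nnz; ++e) {
    const int i = ci[e], g = gi[e];
    const double *ti = &expT[static_cast<size_t>(i) * K];
    const double *bg = &expB[static_cast<size_t>(g) * K];
    double tot = 0.0;
    for (int k = 0; k < K; ++k) {
      s[k] = ti[k] * bg[k];
      tot += s[k];
    }
    const double xe = x[e];
    lik += xe * std::log(tot);
    const double scale = xe / tot;
    for (int k = 0; k < K; ++k) {
      const double a = scale * s[k];
      thetaAcc(i, k) += a;
      betaAcc(g, k) += a;
    }
  }
  return List::create(_["thetaAcc"] = thetaAcc, _["betaAcc"] = betaAcc,
                      _["lik"] = lik);
}

// Cell-side-only allocation used when projecting held-out cells against a
// fixed gene side.
// [[Rcpp::export]]
NumericMatrix hpf_allocate_cells(IntegerVector ci, IntegerVector gi,
                                 NumericVector x, NumericMatrix elogTheta,
                                 NumericMatrix elogBeta) {
  const int K = elogTheta.ncol();
  const int n = elogTheta.nrow();
  const int G = elogBeta.nrow();
  const R_xlen_t nnz = x.size();
  NumericMatrix thetaAcc(n, K);
  std::vector<double> expT(static_cast<size_t>(n) * K);
  std::vector<double> expB(static_cast<size_t>(G) * K);
  for (int k = 0; k < K; ++k) {
    for (int i = 0; i < n; ++i)
      expT[static_cast<size_t>(i) * K + k] = std::exp(elogTheta(i, k));
    for (int g = 0; g < G; ++g)
      expB[static_cast<size_t>(g) * K + k] = std::exp(elogBeta(g, k));
  }
  std::vector<double> s(K);
  for (R_xlen_t e = 0; e < nnz; ++e) {
    const int i = ci[e], g = gi[e];
    const double *ti = &expT[static_cast<size_t>(i) * K];
    const double *bg = &expB[static_cast<size_t>(g) * K];
    double tot = 0.0;
    for (int k = 0; k < K; ++k) {
      s[k] = ti[k] * bg[k];
      tot += s[k];
    }
    const double scale = x[e] / tot;
    for (int k = 0; k < K; ++k) thetaAcc(i, k) += scale * s[k];
  }
  return thetaAcc;
}
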