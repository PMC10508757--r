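// Fused batch-normalization + ReLU kernels (single pass per matrix), used
// by the spot detection model's training loop.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// training-mode forward: batch statistics, normalized activations and the
// ReLU output in one sweep
// [[Rcpp::export(name = ".bnReluFwdCpp")]]
Rcpp::List bnReluFwdCpp(const arma::mat& Z, const arma::vec& gamma,
                        const arma::vec& beta, const double eps) {
  const uword N = Z.n_rows, C = Z.n_cols;
  vec m(C), invstd(C), v(C);
  mat xhat(N, C), out(N, C);
  for (uword c = 0; c < C; ++c) {
    const double* z = Z.colptr(c);
    double s = 0, s2 = 0;
    for (uword i = 0; i < N; ++i) { s += z[i]; s2 += z[i] * z[i]; }
    const double mu = s / N;
    const double var = s2 / N - mu * mu;
    m[c] = mu; v[c] = var;
    const double is = 1.0 / std::sqrt(var + eps);
    invstd[c] = is;
    const double g = gamma[c], b = beta[c];
    double* xh = xhat.colptr(c);
    double* o = out.colptr(c);
    for (uword i = 0; i < N; ++i) {
      const double x = (z[i] - mu) * is;
      xh[i] = x;
      const double y = g * x + b;
      o[i] = y > 0 ? y : 0.0;
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("mean") = m, Rcpp::Named("var") = v,
                            Rcpp::Named("invstd") = invstd);
}

// inference-mode forward with running statistics
// [[Rcpp::export(name = ".bnReluInferCpp")]]
arma::mat bnReluInferCpp(const arma::mat& Z, const arma::vec& gamma,
                         const arma::vec& beta, const arma::vec& runMean,
                         const arma::vec& runVar, const double eps) {
  const uword N = Z.n_rows, C = Z.n_cols;
  mat out(N, C);
  for (uword c = 0; c < C; ++c) {
    const double is = 1.0 / std::sqrt(runVar[c] + eps);
    const double a = gamma[c] * is;
    const double b = beta[c] - runMean[c] * gamma[c] * is;
    const double* z = Z.colptr(c);
    double* o = out.colptr(c);
    for (uword i = 0; i < N; ++i) {
      const double y = a * z[i] + b;
      o[i] = y > 0 ? y : 0.0;
    }
  }
  return out;
}

// backward through ReLU (using the forward output's sign) and batch norm
// [[Rcpp::export(name = ".bnReluBwdCpp")]]
Rcpp::List bnReluBwdCpp(const arma::mat& dA, const arma::mat& out,
                        const arma::mat& xhat, const arma::vec& gamma,
                        const arma::vec& invstd) {
  const uword N = dA.n_rows, C = dA.n_cols;
  mat dZ(N, C);
  vec dGamma(C), dBeta(C);
  for (uword c = 0; c < C; ++c) {
    const double* da = dA.colptr(c);
    const double* o = out.colptr(c);
    const double* xh = xhat.colptr(c);
    double s1 = 0, s2 = 0;
    // first pass: masked sums
    for (uword i = 0; i < N; ++i) {
      const double d = o[i] > 0 ? da[i] : 0.0;
      s1 += d; s2 += d * xh[i];
    }
    dBeta[c] = s1; dGamma[c] = s2;
    const double a = gamma[c] * invstd[c];
    const double m1 = s1 / N, m2 = s2 / N;
    double* dz = dZ.colptr(c);
    for (uword i = 0; i < N; ++i) {
      const double d = o[i] > 0 ? da[i] : 0.0;
      dz[i] = a * (d - m1 - xh[i] * m2);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dZ") = dZ,
                            Rcpp::Named("dGamma") = dGamma,
                            Rcpp::Named("dBeta") = dBeta);
}
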