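// 3x3 same-padding convolution on batched images, via explicit im2col and
// one BLAS product per layer. Activations are matrices of shape
// (H*W*B) x C, rows ordered row-fastest, then column, then image, matching
// the R-side layout. Weights are (9*C) x F with the nine offset blocks
// stacked in (dj, di) order, channels fastest within a block.
//
// The im2col gather copies contiguous runs of H values (one image column at
// one offset), so it is memcpy-bound; the scatter in the backward pass adds
// the same runs back.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// copy A (HWB x C) into padded P (Hp*Wp*B x C layout, flattened per channel)
static void padInto(const mat& A, mat& P, const int H, const int W,
                    const int B) {
  const int Hp = H + 2, Wp = W + 2;
  for (int c = 0; c < (int)A.n_cols; ++c) {
    const double* src = A.colptr(c);
    double* dst = P.colptr(c);
    for (int b = 0; b < B; ++b)
      for (int w = 0; w < W; ++w)
        std::memcpy(dst + 1 + (size_t)(w + 1) * Hp + (size_t)b * Hp * Wp,
                    src + (size_t)w * H + (size_t)b * H * W,
                    sizeof(double) * H);
  }
}

// gather the nine shifted windows of P into X (HWB x 9C)
static void im2col(const mat& P, mat& X, const int H, const int W,
                   const int B, const int C) {
  const int Hp = H + 2, Wp = W + 2;
  int k = 0;
  for (int dj = 0; dj < 3; ++dj)
    for (int di = 0; di < 3; ++di) {
      for (int c = 0; c < C; ++c) {
        const double* src = P.colptr(c);
        double* dst = X.colptr(k * C + c);
        for (int b = 0; b < B; ++b)
          for (int w = 0; w < W; ++w)
            std::memcpy(dst + (size_t)w * H + (size_t)b * H * W,
                        src + di + (size_t)(w + dj) * Hp + (size_t)b * Hp * Wp,
                        sizeof(double) * H);
      }
      ++k;
    }
}

// [[Rcpp::export(name = ".convForwardCpp")]]
arma::mat convForwardCpp(const arma::mat& A, const arma::mat& Wt,
                         const int H, const int W, const int B) {
  const int C = A.n_cols;
  const int Hp = H + 2, Wp = W + 2;
  mat P((size_t)Hp * Wp * B, C, fill::zeros);
  padInto(A, P, H, W, B);
  mat X(A.n_rows, 9 * C);
  im2col(P, X, H, W, B, C);
  return X * Wt;
}

// [[Rcpp::export(name = ".convBackwardCpp")]]
Rcpp::List convBackwardCpp(const arma::mat& A, const arma::mat& Wt,
                           const arma::mat& dZ, const int H, const int W,
                           const int B, const bool needDA) {
  const int C = A.n_cols;
  const int Hp = H + 2, Wp = W + 2;
  mat P((size_t)Hp * Wp * B, C, fill::zeros);
  padInto(A, P, H, W, B);
  mat X(A.n_rows, 9 * C);
  im2col(P, X, H, W, B, C);
  Rcpp::List out;
  out["dW"] = mat(X.t() * dZ);
  if (needDA) {
    const mat dX = dZ * Wt.t();               // HWB x 9C
    mat dP((size_t)Hp * Wp * B, C, fill::zeros);
    int k = 0;
    for (int dj = 0; dj < 3; ++dj)
      for (int di = 0; di < 3; ++di) {
        for (int c = 0; c < C; ++c) {
          const double* src = dX.colptr(k * C + c);
          double* dst = dP.colptr(c);
          for (int b = 0; b < B; ++b)
            for (int w = 0; w < W; ++w) {
              double* d = dst + di + (size_t)(w + dj) * Hp + (size_t)b * Hp * Wp;
              const double* s = src + (size_t)w * H + (size_t)b * H * W;
              for (int h = 0; h < H; ++h) d[h] += s[h];
            }
        }
        ++k;
      }
    mat dA(A.n_rows, C);
    for (int c = 0; c < C; ++c) {
      const double* src = dP.colptr(c);
      double* dst = dA.colptr(c);
      for (int b = 0; b < B; ++b)
        for (int w = 0; w < W; ++w)
          std::memcpy(dst + (size_t)w * H + (size_t)b * H * W,
                      src + 1 + (size_t)(w + 1) * Hp + (size_t)b * Hp * Wp,
                      sizeof(double) * H);
    }
    out["dA"] = dA;
  }
  return out;
}
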