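// Unpadded 1-D convolution over channel-major batches.
//
// A batch is a [C, L*B] matrix: column (b-1)*L + t holds the channel vector
// at position t of sample b. Instead of im2col, the convolution runs K
// shifted GEMMs over the whole concatenated position axis (zero-copy views
// into X, beta = 1 accumulation), then gathers the per-sample valid output
// columns. Output columns that would mix two samples are never gathered, so
// the cross-sample garbage of the full-axis trick is discarded for free.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <cstring>
#ifndef FCONE
#define FCONE
#endif

using Rcpp::NumericMatrix;
using Rcpp::NumericVector;

// [[Rcpp::export]]
NumericMatrix cpp_conv_forward(const NumericMatrix& X,
                               const NumericMatrix& W,
                               const NumericVector& b, int K, int S,
                               int B) {
  const int C = X.nrow();
  const int N = X.ncol();
  const int L_in = N / B;
  const int L_out = (L_in - K) / S + 1;
  const int F = W.nrow();
  const int M = N - K + 1;          // full-axis output width

  std::vector<double> Yfull((size_t)F * M);
  const double one = 1.0, zero = 0.0;
  for (int k = 0; k < K; ++k) {
    const double beta = (k == 0) ? zero : one;
    // W_k: F x C block, X_k: C x M view starting at column k
    F77_CALL(dgemm)("N", "N", &F, &M, &C, &one,
                    &W[(size_t)k * C * F], &F,
                    &X[(size_t)k * C], &C, &beta, Yfull.data(), &F
                    FCONE FCONE);
  }

  NumericMatrix Y(F, L_out * B);
  for (int bb = 0; bb < B; ++bb) {
    for (int t = 0; t < L_out; ++t) {
      const size_t src = (size_t)bb * L_in + (size_t)t * S;
      double* dst = &Y[(size_t)((size_t)bb * L_out + t) * F];
      std::memcpy(dst, Yfull.data() + src * F, F * sizeof(double));
      for (int f = 0; f < F; ++f) dst[f] += b[f];
    }
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv_backward(const NumericMatrix& X,
                             const NumericMatrix& W,
                             const NumericMatrix& dY, int K, int S,
                             int B) {
  const int C = X.nrow();
  const int N = X.ncol();
  const int L_in = N / B;
  const int F = W.nrow();
  const int L_out = dY.ncol() / B;
  const int M = N - K + 1;

  // scatter compact dY back onto the full position axis
  std::vector<double> dYfull((size_t)F * M, 0.0);
  for (int bb = 0; bb < B; ++bb) {
    for (int t = 0; t < L_out; ++t) {
      const size_t dst = (size_t)bb * L_in + (size_t)t * S;
      std::memcpy(dYfull.data() + dst * F,
                  &dY[(size_t)((size_t)bb * L_out + t) * F],
                  F * sizeof(double));
    }
  }

  NumericMatrix dW(F, K * C);
  NumericMatrix dX(C, N);
  NumericVector db(F);
  const double one = 1.0, zero = 0.0;
  for (int k = 0; k < K; ++k) {
    // dW_k = dYfull %*% t(X_k)
    F77_CALL(dgemm)("N", "T", &F, &C, &M, &one, dYfull.data(), &F,
                    &X[(size_t)k * C], &C, &zero,
                    &dW[(size_t)k * C * F], &F FCONE FCONE);
    // dX[, k..k+M-1] += t(W_k) %*% dYfull
    F77_CALL(dgemm)("T", "N", &C, &M, &F, &one,
                    &W[(size_t)k * C * F], &F, dYfull.data(), &F, &one,
                    &dX[(size_t)k * C], &C FCONE FCONE);
  }
  for (size_t j = 0; j < (size_t)dY.ncol(); ++j) {
    const double* col = &dY[j * F];
    for (int f = 0; f < F; ++f) db[f] += col[f];
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dX") = dX);
}
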