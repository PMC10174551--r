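// Fused elementwise kernels for batch normalization, ReLU and masked
// pooling. All matrices are [C, L*B] channel-major batches; `mask` is a
// logical vector over columns (TRUE = real position of some sample).

#include <Rcpp.h>
#include <cstring>

using namespace Rcpp;

// row means and population variances over masked (valid) columns
// [[Rcpp::export]]
List cpp_row_stats_masked(const NumericMatrix& X, const LogicalVector& cm) {
  const int C = X.nrow();
  const R_xlen_t N = X.ncol();
  NumericVector mu(C), va(C);
  R_xlen_t nv = 0;
  for (R_xlen_t j = 0; j < N; ++j) {
    if (!cm[j]) continue;
    ++nv;
    const double* col = &X[j * C];
    for (int c = 0; c < C; ++c) {
      mu[c] += col[c];
      va[c] += col[c] * col[c];
    }
  }
  if (nv == 0) stop("no valid columns");
  for (int c = 0; c < C; ++c) {
    mu[c] /= nv;
    va[c] = va[c] / nv - mu[c] * mu[c];
    if (va[c] < 0) va[c] = 0;
  }
  return List::create(Named("mean") = mu, Named("var") = va,
                      Named("n") = (double)nv);
}

// Y = p*X1 + q*X2 + r per row; columns with mask FALSE are zeroed;
// optionally ReLU-clamped. X2 may be a 0 x 0 matrix when q is unused.
// [[Rcpp::export]]
NumericMatrix cpp_row_affine(const NumericMatrix& X1,
                             const NumericMatrix& X2,
                             const NumericVector& p,
                             const NumericVector& q,
                             const NumericVector& r,
                             const LogicalVector& cm, bool relu) {
  const int C = X1.nrow();
  const R_xlen_t N = X1.ncol();
  const bool use2 = X2.nrow() == C && X2.ncol() == N;
  NumericMatrix Y(C, N);
  for (R_xlen_t j = 0; j < N; ++j) {
    double* y = &Y[j * C];
    if (!cm[j]) continue;                     // already zero
    const double* x1 = &X1[j * C];
    if (use2) {
      const double* x2 = &X2[j * C];
      for (int c = 0; c < C; ++c) y[c] = p[c] * x1[c] + q[c] * x2[c] + r[c];
    } else {
      for (int c = 0; c < C; ++c) y[c] = p[c] * x1[c] + r[c];
    }
    if (relu)
      for (int c = 0; c < C; ++c) { if (y[c] < 0) y[c] = 0; }
  }
  return Y;
}

// row sums over valid columns of A and of A*X (for BN dbeta / dgamma)
// [[Rcpp::export]]
List cpp_row_dots_masked(const NumericMatrix& A, const NumericMatrix& X,
                         const LogicalVector& cm) {
  const int C = A.nrow();
  const R_xlen_t N = A.ncol();
  NumericVector s(C), sx(C);
  for (R_xlen_t j = 0; j < N; ++j) {
    if (!cm[j]) continue;
    const double* a = &A[j * C];
    const double* x = &X[j * C];
    for (int c = 0; c < C; ++c) {
      s[c] += a[c];
      sx[c] += a[c] * x[c];
    }
  }
  return List::create(Named("sum") = s, Named("sum_xprod") = sx);
}

// dX = dY where A > 0 else 0 (ReLU backward)
// [[Rcpp::export]]
NumericMatrix cpp_relu_backward(const NumericMatrix& dY,
                                const NumericMatrix& A) {
  const int C = dY.nrow();
  const R_xlen_t N = dY.ncol();
  NumericMatrix dX(C, N);
  const R_xlen_t n = (R_xlen_t)C * N;
  for (R_xlen_t i = 0; i < n; ++i) dX[i] = (A[i] > 0) ? dY[i] : 0.0;
  return dX;
}

// masked global average pooling: [C, L*B] -> [C, B]
// [[Rcpp::export]]
NumericMatrix cpp_pool_forward(const NumericMatrix& X, int L, int B,
                               const IntegerVector& len) {
  const int C = X.nrow();
  NumericMatrix P(C, B);
  for (int b = 0; b < B; ++b) {
    if (len[b] < 1) stop("sample has no valid positions to pool");
    double* p = &P[(size_t)b * C];
    for (int t = 0; t < len[b]; ++t) {
      const double* col = &X[((size_t)b * L + t) * (size_t)C];
      for (int c = 0; c < C; ++c) p[c] += col[c];
    }
    for (int c = 0; c < C; ++c) p[c] /= len[b];
  }
  return P;
}

// [[Rcpp::export]]
NumericMatrix cpp_pool_backward(const NumericMatrix& dP, int L, int B,
                                const IntegerVector& len) {
  const int C = dP.nrow();
  NumericMatrix dX(C, (size_t)L * B);
  for (int b = 0; b < B; ++b) {
    const double* p = &dP[(size_t)b * C];
    for (int t = 0; t < len[b]; ++t) {
      double* col = &dX[((size_t)b * L + t) * (size_t)C];
      for (int c = 0; c < C; ++c) col[c] = p[c] / len[b];
    }
  }
  return dX;
}

// gather the first L_new columns of every sample: [C, L*B] -> [C, L_new*B]
// [[Rcpp::export]]
NumericMatrix cpp_crop_cols(const NumericMatrix& X, int L, int L_new,
                            int B) {
  const int C = X.nrow();
  NumericMatrix Y(C, (size_t)L_new * B);
  for (int b = 0; b < B; ++b)
    std::memcpy(&Y[(size_t)b * L_new * C], &X[(size_t)b * L * C],
                (size_t)L_new * C * sizeof(double));
  return Y;
}

// scatter gradient back: inverse of cpp_crop_cols
// [[Rcpp::export]]
NumericMatrix cpp_uncrop_cols(const NumericMatrix& dY, int L, int L_new,
                              int B) {
  const int C = dY.nrow();
  NumericMatrix dX(C, (size_t)L * B);
  for (int b = 0; b < B; ++b)
    std::memcpy(&dX[(size_t)b * L * C], &dY[(size_t)b * L_new * C],
                (size_t)L_new * C * sizeof(double));
  return dX;
}

// ReLU forward
// [[Rcpp::export]]
NumericMatrix cpp_relu_forward(const NumericMatrix& X) {
  const R_xlen_t n = (R_xlen_t)X.nrow() * X.ncol();
  NumericMatrix Y(X.nrow(), X.ncol());
  for (R_xlen_t i = 0; i < n; ++i) Y[i] = (X[i] > 0) ? X[i] : 0.0;
  return Y;
}

// ReLU(A + B) with invalid columns zeroed (residual join)
// [[Rcpp::export]]
NumericMatrix cpp_add_relu_masked(const NumericMatrix& A,
                                  const NumericMatrix& Bm,
                                  const LogicalVector& cm) {
  const int C = A.nrow();
  const R_xlen_t N = A.ncol();
  NumericMatrix Y(C, N);
  for (R_xlen_t j = 0; j < N; ++j) {
    if (!cm[j]) continue;
    const double* a = &A[j * C];
    const double* b = &Bm[j * C];
    double* y = &Y[j * C];
    for (int c = 0; c < C; ++c) {
      const double v = a[c] + b[c];
      y[c] = (v > 0) ? v : 0.0;
    }
  }
  return Y;
}
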