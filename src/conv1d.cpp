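// Hot layer primitives for the 1-D segment CNN: im2col / col2im and
// max-pooling, on batches stored sample-major (row = (b-1)*L + pos) with
// one column per channel. Matrix products stay in R (BLAS).

#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& A, int n, int L, int K) {
  const int C = A.ncol();
  const int Lout = L - K + 1;
  NumericMatrix out(no_init(n * Lout, K * C));
  for (int k = 0; k < K; ++k) {
    for (int c = 0; c < C; ++c) {
      const double* src = &A(0, c);
      double* dst = &out(0, k * C + c);
      for (int b = 0; b < n; ++b)
        std::memcpy(dst + b * Lout, src + b * L + k,
                    sizeof(double) * Lout);
    }
  }
  return out;
}

// im2col for a batch stored one sample per ROW (R's n x L matrix),
// with stride on the output positions
// [[Rcpp::export]]
NumericMatrix cpp_im2col_rows(const NumericMatrix& X, int K, int stride) {
  const int n = X.nrow(), L = X.ncol();
  const int Lout = (L - K) / stride + 1;
  NumericMatrix out(no_init(n * Lout, K));
  const double* x = &X(0, 0);
  for (int k = 0; k < K; ++k) {
    double* dst = &out(0, k);
    for (int b = 0; b < n; ++b) {
      double* d = dst + b * Lout;
      const double* s = x + b;          // X(b, i) = x[b + i*n]
      for (int p = 0; p < Lout; ++p)
        d[p] = s[(p * (size_t)stride + k) * (size_t)n];
    }
  }
  return out;
}

// in-place column-wise bias add followed by ReLU
// [[Rcpp::export]]
NumericMatrix cpp_bias_relu(NumericMatrix Z, const NumericVector& b) {
  const int nr = Z.nrow(), nc = Z.ncol();
  for (int c = 0; c < nc; ++c) {
    double* z = &Z(0, c);
    const double bc = b[c];
    for (int i = 0; i < nr; ++i) {
      double v = z[i] + bc;
      z[i] = v > 0 ? v : 0;
    }
  }
  return Z;
}

// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& dXcol, int n, int L, int K,
                         int C) {
  const int Lout = L - K + 1;
  NumericMatrix dA(n * L, C);
  for (int k = 0; k < K; ++k) {
    for (int c = 0; c < C; ++c) {
      const double* src = &dXcol(0, k * C + c);
      double* dst = &dA(0, c);
      for (int b = 0; b < n; ++b) {
        const double* s = src + b * Lout;
        double* d = dst + b * L + k;
        for (int p = 0; p < Lout; ++p) d[p] += s[p];
      }
    }
  }
  return dA;
}

// [[Rcpp::export]]
List cpp_pool_fwd(const NumericMatrix& A, int n, int L, int p) {
  const int C = A.ncol();
  const int P = L / p;
  NumericMatrix M(n * P, C);
  IntegerMatrix amax(n * P, C);
  for (int c = 0; c < C; ++c) {
    const double* src = &A(0, c);
    double* m = &M(0, c);
    int* am = &amax(0, c);
    for (int b = 0; b < n; ++b) {
      const double* s = src + b * L;
      for (int q = 0; q < P; ++q) {
        double best = s[q * p];
        int bi = 1;
        for (int i = 1; i < p; ++i)
          if (s[q * p + i] > best) { best = s[q * p + i]; bi = i + 1; }
        m[b * P + q] = best;
        am[b * P + q] = bi;
      }
    }
  }
  return List::create(_["M"] = M, _["amax"] = amax, _["P"] = P);
}

// [[Rcpp::export]]
NumericMatrix cpp_pool_bwd(const NumericMatrix& dM, const IntegerMatrix& amax,
                           int n, int L, int p) {
  const int C = dM.ncol();
  const int P = L / p;
  NumericMatrix dA(n * L, C);
  for (int c = 0; c < C; ++c) {
    const double* g = &dM(0, c);
    const int* am = &amax(0, c);
    double* d = &dA(0, c);
    for (int b = 0; b < n; ++b)
      for (int q = 0; q < P; ++q)
        d[b * L + q * p + am[b * P + q] - 1] = g[b * P + q];
  }
  return dA;
}
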