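#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
// [[Rcpp::depends(RcppArmadillo)]]
#ifndef FCONE
#define FCONE
#endif

using namespace arma;

// C (m x n) := alpha * op(A) op(B) + beta * C, straight BLAS so the
// accumulating convolutions below run without temporaries.
static void dgemm_raw(const char ta, const char tb, const int m, const int n,
                      const int kk, const double alpha, const double* A,
                      const int lda, const double* B, const int ldb,
                      const double beta, double* C, const int ldc) {
  F77_CALL(dgemm)(&ta, &tb, &m, &n, &kk, &alpha, A, &lda, B, &ldb, &beta,
                  C, &ldc FCONE FCONE);
}

// Shifted-window convolutions along the position (X) axis, channel-first
// layout. Inputs are matrices of shape (channels, Xp * G) where Xp = X + k - 1
// is the zero-padded position axis ("same" convolution) and G independent
// groups (e.g. regulator x batch) are laid out as consecutive column blocks.
// Weights are a cube (channels, filters, k). Output is (filters, X * G):
// out[, x] = sum_d t(W[,,d]) %*% in[, x + d - 1] within each group block.

// All activations live in the padded layout (Xp columns per group block, the
// X core columns at offset padl = (k-1)/2, pad columns kept at exactly zero).
// Because pads are zero on both the inputs and the upstream gradients, each
// kernel offset d reduces to a single wide gemm with a global column shift
// s = d - padl: within-block windows stay inside their block for core
// columns, and cross-block bleed only ever lands on (or comes from) zeroed
// pad columns, which are re-zeroed after the loop.

static void zero_pads(mat& a, const int X, const int G, const int k) {
  const int padl = (k - 1) / 2;
  const int padr = k - 1 - padl;
  const int Xq = X + k - 1;
  for (int g = 0; g < G; ++g) {
    const size_t o = (size_t)g * Xq;
    if (padl > 0) a.cols(o, o + padl - 1).zeros();
    if (padr > 0) a.cols(o + padl + X, o + Xq - 1).zeros();
  }
}

// [[Rcpp::export]]
arma::mat conv_fwd_cpp(const arma::mat& input, const arma::cube& w,
                       const int X, const int G) {
  const int k = w.n_slices;
  const int F = w.n_cols;
  const int padl = (k - 1) / 2;
  const size_t NC = (size_t)(X + k - 1) * G;
  if (input.n_cols != NC)
    Rcpp::stop("conv_fwd: input has %d cols, expected %d", input.n_cols, NC);
  if (input.n_rows != w.n_rows)
    Rcpp::stop("conv_fwd: channel mismatch");
  const int C = w.n_rows;
  mat out(F, NC, fill::zeros);
  for (int d = 0; d < k; ++d) {
    const int s = d - padl;
    const size_t lo = s < 0 ? (size_t)(-s) : 0;
    const size_t hi = s > 0 ? NC - 1 - s : NC - 1;
    const int W = (int)(hi - lo + 1);
    dgemm_raw('T', 'N', F, W, C, 1.0, w.slice(d).memptr(), C,
              input.memptr() + (lo + s) * C, C, 1.0,
              out.memptr() + lo * F, F);
  }
  zero_pads(out, X, G, k);
  return out;
}

// Gradient with respect to the (padded) input; dout must be zero on pads.
// [[Rcpp::export]]
arma::mat conv_bwd_input_cpp(const arma::mat& dout, const arma::cube& w,
                             const int X, const int G) {
  const int k = w.n_slices;
  const int C = w.n_rows;
  const int padl = (k - 1) / 2;
  const size_t NC = (size_t)(X + k - 1) * G;
  if (dout.n_cols != NC)
    Rcpp::stop("conv_bwd_input: dout has %d cols, expected %d", dout.n_cols, NC);
  const int F = w.n_cols;
  mat din(C, NC, fill::zeros);
  for (int d = 0; d < k; ++d) {
    const int s = d - padl;
    const size_t lo = s < 0 ? (size_t)(-s) : 0;
    const size_t hi = s > 0 ? NC - 1 - s : NC - 1;
    const int W = (int)(hi - lo + 1);
    dgemm_raw('N', 'N', C, W, F, 1.0, w.slice(d).memptr(), C,
              dout.memptr() + lo * F, F, 1.0,
              din.memptr() + (lo + s) * C, C);
  }
  return din;
}

// Gradient with respect to the kernel weights; dout must be zero on pads.
// [[Rcpp::export]]
arma::cube conv_bwd_weights_cpp(const arma::mat& input, const arma::mat& dout,
                                const int X, const int G, const int k) {
  const int C = input.n_rows;
  const int F = dout.n_rows;
  const int padl = (k - 1) / 2;
  const size_t NC = (size_t)(X + k - 1) * G;
  if (input.n_cols != NC || dout.n_cols != NC)
    Rcpp::stop("conv_bwd_weights: shape mismatch");
  cube dw(C, F, k);
  for (int d = 0; d < k; ++d) {
    const int s = d - padl;
    const size_t lo = s < 0 ? (size_t)(-s) : 0;
    const size_t hi = s > 0 ? NC - 1 - s : NC - 1;
    const int W = (int)(hi - lo + 1);
    dgemm_raw('N', 'T', C, F, W, 1.0, input.memptr() + (lo + s) * C, C,
              dout.memptr() + lo * F, F, 0.0, dw.slice(d).memptr(), C);
  }
  return dw;
}

// Per-source reductions over the non-margin position bins. `m` is a matrix of
// flattened (X * nsrc) x N tensors, position fastest; rows margin+1..X-margin
// of each source block are reduced. Returns (nsrc x N).

// [[Rcpp::export]]
arma::mat block_max_cpp(const arma::mat& m, const int X, const int margin) {
  const int nsrc = m.n_rows / X;
  const int N = m.n_cols;
  if ((int)m.n_rows != X * nsrc) Rcpp::stop("block_max: nrow not a multiple of X");
  mat out(nsrc, N);
  for (int j = 0; j < N; ++j) {
    for (int s = 0; s < nsrc; ++s) {
      const size_t o = (size_t)s * X;
      double mx = -datum::inf;
      for (int x = margin; x < X - margin; ++x) {
        const double v = m(o + x, j);
        if (v > mx) mx = v;
      }
      out(s, j) = mx;
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::mat block_mean_cpp(const arma::mat& m, const int X, const int margin) {
  const int nsrc = m.n_rows / X;
  const int N = m.n_cols;
  const int span = X - 2 * margin;
  if (span <= 0) Rcpp::stop("block_mean: margin too large");
  mat out(nsrc, N);
  for (int j = 0; j < N; ++j) {
    for (int s = 0; s < nsrc; ++s) {
      const size_t o = (size_t)s * X;
      double acc = 0.0;
      for (int x = margin; x < X - margin; ++x) acc += m(o + x, j);
      out(s, j) = acc / span;
    }
  }
  return out;
}
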