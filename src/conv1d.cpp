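// 1D "same" convolution (stride 1, odd kernel, zero padding) for feature
// cubes laid out as (channels, length, batch).  Implemented as im2col + GEMM
// so the heavy lifting runs through BLAS.  Weight matrix W is
// (C_out, C_in * K) with column index c_in * K + k for tap k of channel c_in.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void im2col_slice(const mat& x, int K, mat& out) {
  const int C = x.n_rows, L = x.n_cols, pad = (K - 1) / 2;
  // out is (C*K, L), pre-allocated
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < K; ++k) {
      const int shift = k - pad;  // source column = l + shift
      double* dst = out.memptr() + (c * K + k);  // row (c*K + k)
      const int nrow = out.n_rows;
      for (int l = 0; l < L; ++l) {
        const int s = l + shift;
        dst[(size_t)l * nrow] =
            (s >= 0 && s < L) ? x.at(c, s) : 0.0;
      }
    }
  }
}

static void col2im_slice(const mat& m, int K, mat& out) {
  const int C = out.n_rows, L = out.n_cols, pad = (K - 1) / 2;
  out.zeros();
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < K; ++k) {
      const int shift = k - pad;
      const double* src = m.memptr() + (c * K + k);
      const int nrow = m.n_rows;
      for (int l = 0; l < L; ++l) {
        const int s = l + shift;
        if (s >= 0 && s < L) out.at(c, s) += src[(size_t)l * nrow];
      }
    }
  }
}

// [[Rcpp::export(name = ".conv1d_forward")]]
arma::cube conv1d_forward(const arma::cube& x, const arma::mat& w,
                          const arma::vec& b, int K) {
  const int L = x.n_cols, B = x.n_slices, Cin = x.n_rows, Cout = w.n_rows;
  if ((int)w.n_cols != Cin * K)
    Rcpp::stop("weight matrix has %d columns, expected C_in * K = %d",
               (int)w.n_cols, Cin * K);
  cube y(Cout, L, B);
  mat cols(Cin * K, L);
  for (int s = 0; s < B; ++s) {
    im2col_slice(x.slice(s), K, cols);
    y.slice(s) = w * cols;
    y.slice(s).each_col() += b;
  }
  return y;
}

// [[Rcpp::export(name = ".conv1d_backward")]]
Rcpp::List conv1d_backward(const arma::cube& x, const arma::mat& w,
                           const arma::cube& dy, int K) {
  const int L = x.n_cols, B = x.n_slices, Cin = x.n_rows;
  mat dw(w.n_rows, w.n_cols, fill::zeros);
  vec db(w.n_rows, fill::zeros);
  cube dx(Cin, L, B);
  mat cols(Cin * K, L);
  mat dxs(Cin, L);
  for (int s = 0; s < B; ++s) {
    im2col_slice(x.slice(s), K, cols);
    dw += dy.slice(s) * cols.t();
    db += sum(dy.slice(s), 1);
    col2im_slice(w.t() * dy.slice(s), K, dxs);
    dx.slice(s) = dxs;
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}
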