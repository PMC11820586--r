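// 1D convolution kernels (zero padding, stride 1) used by the network.
// Feature maps are stored as channels x length matrices; weights for a
// convolution c_in -> c_out with odd kernel k are a c_out x (c_in * k)
// matrix, so both directions reduce to one GEMM against an im2col buffer.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col1d(const mat& x, const int k) {
  const int cin = x.n_rows, L = x.n_cols, pad = (k - 1) / 2;
  mat cols(cin * k, L, fill::zeros);
  for (int j = 0; j < k; ++j) {
    const int off = j - pad;  // source column offset
    const int t0 = std::max(0, -off), t1 = std::min<int>(L, L - off);
    if (t1 <= t0) continue;
    cols.rows(j * cin, j * cin + cin - 1).cols(t0, t1 - 1) =
        x.cols(t0 + off, t1 - 1 + off);
  }
  return cols;
}

static mat col2im1d(const mat& cols, const int k, const int cin, const int L) {
  const int pad = (k - 1) / 2;
  mat x(cin, L, fill::zeros);
  for (int j = 0; j < k; ++j) {
    const int off = j - pad;
    const int t0 = std::max(0, -off), t1 = std::min<int>(L, L - off);
    if (t1 <= t0) continue;
    x.cols(t0 + off, t1 - 1 + off) +=
        cols.rows(j * cin, j * cin + cin - 1).cols(t0, t1 - 1);
  }
  return x;
}

// [[Rcpp::export(name = ".conv1d_fw")]]
arma::mat conv1d_fw(const arma::mat& x, const arma::mat& W,
                    const arma::vec& b, const int k) {
  mat out = W * im2col1d(x, k);
  out.each_col() += b;
  return out;
}

// gradient w.r.t. the input map
// [[Rcpp::export(name = ".conv1d_bw_x")]]
arma::mat conv1d_bw_x(const arma::mat& gout, const arma::mat& W, const int k,
                      const int cin) {
  mat gcols = W.t() * gout;
  return col2im1d(gcols, k, cin, gout.n_cols);
}

// gradient w.r.t. the weight matrix
// [[Rcpp::export(name = ".conv1d_bw_w")]]
arma::mat conv1d_bw_w(const arma::mat& gout, const arma::mat& x, const int k) {
  return gout * im2col1d(x, k).t();
}
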