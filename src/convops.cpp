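#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Images are H x W x C cubes (double). Convolution weights are stored as a
// (Cout) x (Cin*k*k) matrix whose row oc, entry c*k*k + ki*k + kj, multiplies
// input channel c at kernel offset (ki, kj). Spatial output positions are
// flattened column-major (idx = oi + oj*Ho) so slices reshape without copies.

static mat im2col(const cube& x, const int k, const int stride, const int pad,
                  const int Ho, const int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out(C * k * k, Ho * Wo, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int ki = 0; ki < k; ++ki) {
      for (int kj = 0; kj < k; ++kj) {
        const int row = c * k * k + ki * k + kj;
        for (int oj = 0; oj < Wo; ++oj) {
          const int jj = oj * stride + kj - pad;
          if (jj < 0 || jj >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int ii = oi * stride + ki - pad;
            if (ii < 0 || ii >= H) continue;
            out(row, oi + oj * Ho) = xs(ii, jj);
          }
        }
      }
    }
  }
  return out;
}

static void col2im_acc(cube& dx, const mat& cols, const int k, const int stride,
                       const int pad, const int Ho, const int Wo) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  for (int c = 0; c < C; ++c) {
    mat& xs = dx.slice(c);
    for (int ki = 0; ki < k; ++ki) {
      for (int kj = 0; kj < k; ++kj) {
        const int row = c * k * k + ki * k + kj;
        for (int oj = 0; oj < Wo; ++oj) {
          const int jj = oj * stride + kj - pad;
          if (jj < 0 || jj >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int ii = oi * stride + ki - pad;
            if (ii < 0 || ii >= H) continue;
            xs(ii, jj) += cols(row, oi + oj * Ho);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv2d_forward(const arma::cube& x, const arma::mat& Wm,
                          const arma::vec& b, const int k, const int stride,
                          const int pad) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int Cout = Wm.n_rows;
  mat cols = im2col(x, k, stride, pad, Ho, Wo);
  mat y = Wm * cols;              // Cout x (Ho*Wo)
  y.each_col() += b;
  cube out(Ho, Wo, Cout);
  for (int oc = 0; oc < Cout; ++oc)
    out.slice(oc) = reshape(y.row(oc).t(), Ho, Wo);
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv2d_backward(const arma::cube& x, const arma::mat& Wm,
                           const arma::cube& gy, const int k, const int stride,
                           const int pad) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, Cout = gy.n_slices;
  mat G(Cout, Ho * Wo);
  for (int oc = 0; oc < Cout; ++oc)
    G.row(oc) = vectorise(gy.slice(oc)).t();
  mat cols = im2col(x, k, stride, pad, Ho, Wo);
  mat dW = G * cols.t();
  vec db = sum(G, 1);
  mat dcols = Wm.t() * G;
  cube dx(x.n_rows, x.n_cols, x.n_slices, fill::zeros);
  col2im_acc(dx, dcols, k, stride, pad, Ho, Wo);
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
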