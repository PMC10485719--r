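// Minimal 2-D convolution kernels (im2col formulation) used by the CNN engine.
// Layout conventions, shared with the R side:
//   * images / feature maps are H x W x C cubes;
//   * a conv weight is a (kh*kw*in_ch) x out_ch matrix whose rows are ordered
//     channel-major: row = c*kh*kw + kj*kh + ki  (ki over kernel rows,
//     kj over kernel cols, c over input channels), so the rows belonging to
//     one input channel form a contiguous block — input-channel expansion
//     appends a block of kh*kw rows.
//   * im2col column j corresponds to output position (ho, wo) with
//     j = wo*Ho + ho (column-major over the output grid).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

static mat im2col(const cube &X, int kh, int kw, int stride, int pad,
                  int Ho, int Wo) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  mat cols(kh * kw * C, Ho * Wo, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat &Xc = X.slice(c);
    const int roff = c * kh * kw;
    for (int wo = 0; wo < Wo; ++wo) {
      const int wi0 = wo * stride - pad;
      for (int ho = 0; ho < Ho; ++ho) {
        const int hi0 = ho * stride - pad;
        const int col = wo * Ho + ho;
        for (int kj = 0; kj < kw; ++kj) {
          const int wi = wi0 + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            const int hi = hi0 + ki;
            if (hi < 0 || hi >= H) continue;
            cols(roff + kj * kh + ki, col) = Xc(hi, wi);
          }
        }
      }
    }
  }
  return cols;
}

static void col2im_add(mat &dX_flat, const mat &dcols, int H, int W, int C,
                       int kh, int kw, int stride, int pad, int Ho, int Wo) {
  // dX_flat is H*W x C (column per channel), accumulated in place
  for (int c = 0; c < C; ++c) {
    const int roff = c * kh * kw;
    for (int wo = 0; wo < Wo; ++wo) {
      const int wi0 = wo * stride - pad;
      for (int ho = 0; ho < Ho; ++ho) {
        const int hi0 = ho * stride - pad;
        const int col = wo * Ho + ho;
        for (int kj = 0; kj < kw; ++kj) {
          const int wi = wi0 + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            const int hi = hi0 + ki;
            if (hi < 0 || hi >= H) continue;
            dX_flat(wi * H + hi, c) += dcols(roff + kj * kh + ki, col);
          }
        }
      }
    }
  }
}

// Forward pass of one conv layer: Y(:,:,o) = sum_c X * W + b[o]
// [[Rcpp::export]]
arma::cube conv2d_forward(const arma::cube &X, const arma::mat &W,
                          const arma::vec &b, int kh, int kw, int stride,
                          int pad) {
  const int Ho = out_size(X.n_rows, kh, stride, pad);
  const int Wo = out_size(X.n_cols, kw, stride, pad);
  const int Co = W.n_cols;
  mat cols = im2col(X, kh, kw, stride, pad, Ho, Wo);
  mat Y = W.t() * cols;           // Co x (Ho*Wo)
  Y.each_col() += b;
  cube out(Ho, Wo, Co);
  for (int o = 0; o < Co; ++o)
    out.slice(o) = reshape(Y.row(o), Ho, Wo);
  return out;
}

// Backward pass: given upstream gradient dY (Ho x Wo x Co), returns
// dW, db, and (optionally) dX.
// [[Rcpp::export]]
Rcpp::List conv2d_backward(const arma::cube &X, const arma::mat &W,
                           const arma::cube &dY, int kh, int kw, int stride,
                           int pad, bool need_dx) {
  const int H = X.n_rows, Wd = X.n_cols, C = X.n_slices;
  const int Ho = dY.n_rows, Wo = dY.n_cols, Co = dY.n_slices;
  mat dYmat(Co, Ho * Wo);
  for (int o = 0; o < Co; ++o)
    dYmat.row(o) = vectorise(dY.slice(o)).t();
  mat cols = im2col(X, kh, kw, stride, pad, Ho, Wo);
  mat dW = cols * dYmat.t();      // (kh*kw*C) x Co
  vec db = sum(dYmat, 1);
  Rcpp::List res = Rcpp::List::create(Rcpp::Named("dW") = dW,
                                      Rcpp::Named("db") = db);
  if (need_dx) {
    mat dcols = W * dYmat;        // (kh*kw*C) x (Ho*Wo)
    mat dX_flat(H * Wd, C, fill::zeros);
    col2im_add(dX_flat, dcols, H, Wd, C, kh, kw, stride, pad, Ho, Wo);
    cube dX(H, Wd, C);
    for (int c = 0; c < C; ++c)
      dX.slice(c) = reshape(dX_flat.col(c), H, Wd);
    res["dX"] = dX;
  }
  return res;
}
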