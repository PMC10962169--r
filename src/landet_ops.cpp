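// Batched im2col / col2im kernels for 3x3 convolutions with padding 1.
//
// Feature maps are stored channels-first as C x (B*H*W) matrices whose
// column index is b*(H*W) + x*H + y (0-based), i.e. each image occupies a
// contiguous block of columns in R's column-major order. im2col expands a
// batch into a (C*9) x (B*Ho*Wo) patch matrix so the convolution becomes a
// single BLAS matrix product; col2im is its adjoint, used in
// backpropagation. Row index within a patch column is c*9 + kx*3 + ky.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
arma::mat im2col_batch(const arma::mat& X, int B, int H, int W, int stride) {
  const int C = X.n_rows;
  const int Ho = H / stride, Wo = W / stride;
  mat out(C * 9, (size_t)B * Ho * Wo, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const size_t in0 = (size_t)b * H * W;
    const size_t out0 = (size_t)b * Ho * Wo;
    for (int xo = 0; xo < Wo; ++xo) {
      for (int yo = 0; yo < Ho; ++yo) {
        const size_t oc = out0 + (size_t)xo * Ho + yo;
        const int xc = xo * stride, yc = yo * stride;
        for (int kx = 0; kx < 3; ++kx) {
          const int xi = xc + kx - 1;
          if (xi < 0 || xi >= W) continue;
          for (int ky = 0; ky < 3; ++ky) {
            const int yi = yc + ky - 1;
            if (yi < 0 || yi >= H) continue;
            const size_t ic = in0 + (size_t)xi * H + yi;
            const int r0 = kx * 3 + ky;
            const double* src = X.colptr(ic);
            double* dst = out.colptr(oc) + r0;
            for (int c = 0; c < C; ++c)
              dst[c * 9] = src[c];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::mat col2im_batch(const arma::mat& dCol, int B, int H, int W,
                       int stride) {
  const int C = dCol.n_rows / 9;
  const int Ho = H / stride, Wo = W / stride;
  mat out(C, (size_t)B * H * W, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const size_t in0 = (size_t)b * H * W;
    const size_t out0 = (size_t)b * Ho * Wo;
    for (int xo = 0; xo < Wo; ++xo) {
      for (int yo = 0; yo < Ho; ++yo) {
        const size_t oc = out0 + (size_t)xo * Ho + yo;
        const int xc = xo * stride, yc = yo * stride;
        for (int kx = 0; kx < 3; ++kx) {
          const int xi = xc + kx - 1;
          if (xi < 0 || xi >= W) continue;
          for (int ky = 0; ky < 3; ++ky) {
            const int yi = yc + ky - 1;
            if (yi < 0 || yi >= H) continue;
            const size_t ic = in0 + (size_t)xi * H + yi;
            const int r0 = kx * 3 + ky;
            const double* src = dCol.colptr(oc) + r0;
            double* dst = out.colptr(ic);
            for (int c = 0; c < C; ++c)
              dst[c] += src[c * 9];
          }
        }
      }
    }
  }
  return out;
}
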