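// Valid (no-padding) strided 3D convolution over (y, x, t) with input channels,
// implemented as im2col + GEMM so that the BLAS carries the arithmetic.
// Layout conventions (match the R side):
//   input  x : 4D array dim (Y, X, T, I), column-major
//   kernels  : passed as a matrix wmat of dim (ky*kx*kt*I) x J, where each
//              column is the column-major vec of a (ky, kx, kt, I) kernel
//   output H : returned as a matrix (Yh*Xh*Th) x J whose rows enumerate output
//              positions in column-major (yh fastest, then xh, then th) order,
//              i.e. vec-compatible with an R array dim (Yh, Xh, Th, J).
// The operation is cross-correlation (no kernel flip), the usual convention
// for learned convolutional layers.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void out_dims(const IntegerVector& xdim, const IntegerVector& kdim,
                     const IntegerVector& stride, int& Yh, int& Xh, int& Th) {
  Yh = (xdim[0] - kdim[0]) / stride[0] + 1;
  Xh = (xdim[1] - kdim[1]) / stride[1] + 1;
  Th = (xdim[2] - kdim[2]) / stride[2] + 1;
  if (xdim[0] < kdim[0] || xdim[1] < kdim[1] || xdim[2] < kdim[2])
    stop("kernel exceeds input extent");
}

static arma::mat im2col(const arma::vec& x, const IntegerVector& xdim,
                        const IntegerVector& kdim, const IntegerVector& stride) {
  const int Y = xdim[0], X = xdim[1], T = xdim[2], I = xdim[3];
  const int ky = kdim[0], kx = kdim[1], kt = kdim[2];
  const int sy = stride[0], sx = stride[1], st = stride[2];
  int Yh, Xh, Th;
  out_dims(xdim, kdim, stride, Yh, Xh, Th);
  const arma::uword npos = (arma::uword)Yh * Xh * Th;
  arma::mat P(npos, (arma::uword)ky * kx * kt * I);
  arma::uword c = 0;
  for (int i = 0; i < I; ++i)
    for (int dt = 0; dt < kt; ++dt)
      for (int dx = 0; dx < kx; ++dx)
        for (int dy = 0; dy < ky; ++dy, ++c) {
          double* col = P.colptr(c);
          arma::uword p = 0;
          for (int th = 0; th < Th; ++th) {
            const arma::uword toff =
              ((arma::uword)i * T + (arma::uword)(th * st + dt)) * X * Y;
            for (int xh = 0; xh < Xh; ++xh) {
              const arma::uword base = toff + (arma::uword)(xh * sx + dx) * Y + dy;
              const double* src = x.memptr() + base;
              for (int yh = 0; yh < Yh; ++yh, ++p) col[p] = src[yh * sy];
            }
          }
        }
  return P;
}

// scatter-add the adjoint of im2col: dP -> dx
static arma::vec col2im(const arma::mat& dP, const IntegerVector& xdim,
                        const IntegerVector& kdim, const IntegerVector& stride) {
  const int Y = xdim[0], X = xdim[1], T = xdim[2], I = xdim[3];
  const int ky = kdim[0], kx = kdim[1], kt = kdim[2];
  const int sy = stride[0], sx = stride[1], st = stride[2];
  int Yh, Xh, Th;
  out_dims(xdim, kdim, stride, Yh, Xh, Th);
  arma::vec dx((arma::uword)Y * X * T * I, arma::fill::zeros);
  arma::uword c = 0;
  for (int i = 0; i < I; ++i)
    for (int dt = 0; dt < kt; ++dt)
      for (int dx_ = 0; dx_ < kx; ++dx_)
        for (int dy = 0; dy < ky; ++dy, ++c) {
          const double* col = dP.colptr(c);
          arma::uword p = 0;
          for (int th = 0; th < Th; ++th) {
            const arma::uword toff =
              ((arma::uword)i * T + (arma::uword)(th * st + dt)) * X * Y;
            for (int xh = 0; xh < Xh; ++xh) {
              const arma::uword base = toff + (arma::uword)(xh * sx + dx_) * Y + dy;
              double* dst = dx.memptr() + base;
              for (int yh = 0; yh < Yh; ++yh, ++p) dst[yh * sy] += col[p];
            }
          }
        }
  return dx;
}

// [[Rcpp::export(name = ".cppConv3d")]]
arma::mat cppConv3d(const arma::vec& x, const IntegerVector& xdim,
                    const arma::mat& wmat, const IntegerVector& kdim,
                    const IntegerVector& stride) {
  if ((arma::uword)xdim[0] * xdim[1] * xdim[2] * xdim[3] != x.n_elem)
    stop("input length does not match its declared dimensions");
  if (wmat.n_rows != (arma::uword)kdim[0] * kdim[1] * kdim[2] * xdim[3])
    stop("kernel matrix rows do not match kernel dims x input channels");
  arma::mat P = im2col(x, xdim, kdim, stride);
  return P * wmat;
}

// [[Rcpp::export(name = ".cppConv3dBackward")]]
List cppConv3dBackward(const arma::vec& x, const IntegerVector& xdim,
                       const arma::mat& wmat, const IntegerVector& kdim,
                       const IntegerVector& stride, const arma::mat& dH,
                       const bool need_dx) {
  arma::mat P = im2col(x, xdim, kdim, stride);
  arma::mat dW = P.t() * dH;
  if (!need_dx) return List::create(Named("dW") = dW);
  arma::mat dP = dH * wmat.t();
  arma::vec dx = col2im(dP, xdim, kdim, stride);
  return List::create(Named("dW") = dW, Named("dx") = dx);
}

// Fractionally-strided (transposed) convolution: the adjoint of the strided
// valid cross-correlation that maps a (Y, X, T, K) tensor to (Yh, Xh, Th, J)
// with kernels (ky, kx, kt, K, J). Given hidden activity H as its
// (Yh*Xh*Th) x J matrix and the kernel matrix mmat ((ky*kx*kt*K) x J),
// returns vec of the (Y, X, T, K) output = col2im(H * mmat^T). Equivalent to
// zero-dilating H by the stride, padding by kernel-1, and cross-correlating
// with the spatially flipped, channel-transposed kernels -- without ever
// materializing the dilated tensor.
// [[Rcpp::export(name = ".cppConvTranspose")]]
arma::vec cppConvTranspose(const arma::mat& H, const IntegerVector& outdim,
                           const arma::mat& mmat, const IntegerVector& kdim,
                           const IntegerVector& stride) {
  if (mmat.n_rows != (arma::uword)kdim[0] * kdim[1] * kdim[2] * outdim[3])
    stop("kernel matrix rows do not match kernel dims x output channels");
  arma::mat dP = H * mmat.t();
  return col2im(dP, outdim, kdim, stride);
}
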