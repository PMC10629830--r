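# Internal numeric helpers shared across modules.

relu <- function(x) pmax(x, 0)

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# promote a 3D (y, x, t) tensor to 4D with a singleton channel axis
as4d <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("expected a 3D or 4D array")
  x
}

# kernels as the (ky*kx*kt*I) x J matrix the C++ convolution consumes
wAsMatrix <- function(W) {
  d <- dim(W)
  matrix(W, nrow = prod(d[1:4]), ncol = d[5])
}

# Zero-dilate hidden activity spatially by the stride and zero-pad the spatial
# borders by (kernel - 1): valid convolution of the result with the output
# kernels is the fractionally-strided (transposed) convolution whose output
# spatial size is (Yh - 1) * sy + ky, the input frame size. Temporal stride is
# 1 in every stack, so time is never dilated.
dilatePad <- function(H, stride, kernel) {
  d <- dim(H)
  sy <- stride[1]; sx <- stride[2]
  ky <- kernel[1]; kx <- kernel[2]
  Yd <- (d[1] - 1L) * sy + 1L + 2L * (ky - 1L)
  Xd <- (d[2] - 1L) * sx + 1L + 2L * (kx - 1L)
  out <- array(0, dim = c(Yd, Xd, d[3], d[4]))
  iy <- (seq_len(d[1]) - 1L) * sy + ky
  ix <- (seq_len(d[2]) - 1L) * sx + kx
  out[iy, ix, , ] <- H
  out
}

# Adjoint-form output kernels: the transposed convolution computes
# col2im(H %*% t(mTilde)) with mTilde the spatially flipped, channel-swapped
# version of the output kernels M (an involution, so it is its own inverse).
mTilde <- function(M) {
  d <- dim(M)
  aperm(M[d[1]:1, d[2]:1, , , , drop = FALSE], c(1, 2, 3, 5, 4))
}

# fractionally-strided convolution of hidden activity with output kernels M
# (ky, kx, 1, J, K): equals valid cross-correlation of the stride-dilated,
# (kernel-1)-padded H with M, computed without materializing the dilation
convTransposed <- function(H, M, stride) {
  d <- dim(H)
  kd <- dim(M)
  outdim <- c((d[1:2] - 1L) * stride[1:2] + kd[1:2], d[3], kd[5])
  V <- .cppConvTranspose(matrix(H, ncol = d[4]), as.integer(outdim),
                         wAsMatrix(mTilde(M)), as.integer(c(kd[1:2], 1L)),
                         as.integer(stride))
  array(V, dim = outdim)
}

# strided valid 3D convolution returning an (Yh, Xh, Th, J) array
conv3d <- function(x, W, stride) {
  x <- as4d(x)
  d <- dim(x); kd <- dim(W)
  if (d[4] != kd[4]) stop("input channel axis does not match kernels")
  H <- .cppConv3d(as.numeric(x), as.integer(d), wAsMatrix(W),
                  as.integer(kd[1:3]), as.integer(stride))
  hd <- floor((d[1:3] - kd[1:3]) / stride) + 1L
  array(H, dim = c(hd, kd[5]))
}

# sum of |w| over every kernel entry
l1norm <- function(x) sum(abs(x))

stopIfNaN <- function(..., what = "tensor") {
  for (x in list(...)) if (anyNA(x) || any(is.nan(x)))
    stop(sprintf("NaN/NA encountered in %s", what))
  invisible(NULL)
}

# deterministic child seeds below 2^31 derived from one user seed
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 9973 * k) %% 2147483647)
}
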