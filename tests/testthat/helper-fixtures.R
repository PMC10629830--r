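# Shared fixtures: brute-force oracles and hand-built units.

# six-nested-loop valid strided cross-correlation oracle, independent of the
# package's im2col path
bruteConv3d <- function(x, W, stride) {
  d <- dim(x); k <- dim(W)
  hd <- floor((d[1:3] - k[1:3]) / stride) + 1
  H <- array(0, c(hd, k[5]))
  for (j in seq_len(k[5])) for (yh in seq_len(hd[1]))
    for (xh in seq_len(hd[2])) for (th in seq_len(hd[3])) {
      acc <- 0
      for (i in seq_len(d[4]))
        for (dy in seq_len(k[1])) for (dx in seq_len(k[2]))
          for (dt in seq_len(k[3]))
            acc <- acc + x[(yh - 1) * stride[1] + dy, (xh - 1) * stride[2] + dx,
                           (th - 1) * stride[3] + dt, i] * W[dy, dx, dt, i, j]
      H[yh, xh, th, j] <- acc
    }
  H
}

# reference fractionally-strided head: explicit dilation + padding + brute conv
brutePredict <- function(H, M, stride, kernel) {
  Hd <- TemporalPrediction:::dilatePad(H, stride, kernel)
  bruteConv3d(Hd, M, c(1, 1, 1))
}

# 2D Gabor on a size x size grid (for planted filters)
gaborPatch <- function(size, thetaDeg, f, sigma, phase = 0, A = 1,
                       center = (size + 1) / 2) {
  th <- thetaDeg * pi / 180
  xg <- matrix(seq_len(size), size, size, byrow = TRUE) - center
  yg <- matrix(seq_len(size), size, size) - center
  xr <- xg * cos(th) + yg * sin(th)
  yr <- -xg * sin(th) + yg * cos(th)
  A * exp(-(xr / (2 * sigma))^2 - (yr / (2 * sigma))^2) *
    cos(2 * pi * f * xr + phase)
}

# difference-of-Gaussians center-surround patch
dogPatch <- function(size, sigmaC = 1.5, sigmaS = 3.5, A = 1) {
  c0 <- (size + 1) / 2
  xg <- matrix(seq_len(size), size, size, byrow = TRUE) - c0
  yg <- matrix(seq_len(size), size, size) - c0
  r2 <- xg^2 + yg^2
  A * (exp(-r2 / (2 * sigmaC^2)) -
         (sigmaC^2 / sigmaS^2) * exp(-r2 / (2 * sigmaS^2)))
}

# one-stack model holding given spatial filters as unit kernels (linear+relu
# units at stride 1, no temporal structure unless depth > 1 slices given)
filterBankModel <- function(filters, inputSide, clipLen = 12L, depth = 1L) {
  J <- length(filters)
  k <- dim(filters[[1]])[1]
  spec <- stackSpec(1L, c(inputSide, inputSide, clipLen, 1L), J,
                    c(k, k, depth), c(1L, 1L, 1L))
  W <- array(0, dim = c(k, k, depth, 1L, J))
  for (j in seq_len(J)) {
    fj <- filters[[j]]
    if (length(dim(fj)) == 2L) W[, , depth, 1L, j] <- fj
    else W[, , , 1L, j] <- fj
  }
  M <- array(0, dim = c(k, k, 1L, J, 1L))
  wts <- new("StackWeights", W = W, b = numeric(J), M = M, c = 0)
  new("HierarchicalModel", specs = list(spec), weights = list(wts),
      trainingLog = list(), objective = "prediction")
}

# deterministic small translating-texture clip set for light training tests
tinyClips <- function(n = 12, side = 24L, seed = 5) {
  synthMovies(n, side = side, seed = seed, velocityRange = 2)
}
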