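# Receptive-field estimation: stack-1 kernels read directly (the unit is a
# linear-nonlinear cascade), deeper units probed by reverse correlation with
# binary noise.

# a closure returning the activity trace of one unit for a (y, x, t) stimulus:
# the spatially central hidden unit of the channel, at all valid time steps.
# `model` may also be a plain function(stimulus) -> trace (a synthetic unit).
.unitResponder <- function(model, stack = 1L, unit = 1L) {
  if (is.function(model)) return(model)
  force(stack); force(unit)
  function(stim) {
    H <- forwardHierarchy(model, stim, upTo = stack)[[stack]]
    d <- dim(H)
    H[ceiling(d[1] / 2), ceiling(d[2] / 2), , unit]
  }
}

#' Stack-1 receptive field read from the input weights
#'
#' The first stack is a linear-nonlinear cascade, so the input kernel of a
#' unit is its linear RF.
#'
#' @param model a [HierarchicalModel-class].
#' @param unit convolutional unit index.
#' @param stack must be 1 (deeper stacks need [rfByReverseCorrelation()]).
#' @return a [ReceptiveField-class]; lag depth equals the kernel's temporal
#'   size, most recent lag last
#' @export
rfFromWeights <- function(model, unit, stack = 1L) {
  if (stack != 1L)
    stop("weights are a linear RF only for stack 1; use reverse correlation")
  W <- model@weights[[1]]@W
  rf <- W[, , , 1L, unit]
  dim(rf) <- dim(W)[1:3]
  new("ReceptiveField", weights = rf, source = "stack1_weights",
      unitId = c(1L, as.integer(unit)))
}

#' Receptive fields of a whole stack by reverse correlation
#'
#' Presents `nSamples` binary-noise stimuli (+/- amplitude) sized to the
#' stack's receptive extent, so each probed unit responds with exactly one
#' hidden sample per stimulus, and computes the response-weighted average of
#' the noise (a spike-triggered-average analogue with graded activity),
#' normalized by the summed response. Units with identically zero response
#' are flagged undefined rather than silently zeroed.
#'
#' @param model a [HierarchicalModel-class].
#' @param stack stack index (>= 2 is the intended use; 1 works but the weights
#'   are already the RF).
#' @param nSamples number of noise samples (reference setting 100000).
#' @param seed RNG seed.
#' @param amplitude noise amplitude (default 3).
#' @param chunk samples per generation block.
#' @return list of [ReceptiveField-class], one per convolutional unit
#' @export
reverseCorrelationRFs <- function(model, stack, nSamples = 1e5, seed = 1L,
                                  amplitude = 3, chunk = 2000L) {
  ext <- receptiveExtent(model@specs[seq_len(stack)])
  J <- model@specs[[stack]]@convUnits
  accMat <- matrix(0, ext[1] * ext[2] * ext[3], J)
  rsum <- numeric(J)
  done <- 0L
  k <- 0L
  while (done < nSamples) {
    k <- k + 1L
    nb <- min(chunk, nSamples - done)
    noise <- makeBinaryNoise(nb, ext[1], ext[3], amplitude,
                             seed = childSeed(seed, k))
    dim(noise) <- c(ext[1], ext[1], ext[3], nb)
    for (s in seq_len(nb)) {
      stim <- noise[, , , s, drop = FALSE]
      dim(stim) <- c(ext[1], ext[1], ext[3])
      H <- forwardHierarchy(model, stim, upTo = stack)[[stack]]
      r <- H[1, 1, 1, ] # extent-sized input leaves a single hidden sample
      nz <- which(r != 0)
      if (length(nz))
        accMat[, nz] <- accMat[, nz] + as.numeric(stim) %o% r[nz]
      rsum <- rsum + r
    }
    done <- done + nb
  }
  lapply(seq_len(J), function(j) {
    if (rsum[j] == 0)
      return(new("ReceptiveField",
                 weights = array(NA_real_, dim = unname(ext)),
                 source = "reverse_correlation",
                 unitId = c(as.integer(stack), j), defined = FALSE))
    new("ReceptiveField",
        weights = array(accMat[, j] / rsum[j], dim = unname(ext)),
        source = "reverse_correlation", unitId = c(as.integer(stack), j))
  })
}

#' Reverse-correlation RF of a single unit
#'
#' @inheritParams reverseCorrelationRFs
#' @param unit unit index, ignored when `model` is a plain response function
#'   (a synthetic unit mapping a (y, x, t) stimulus to a scalar or trace).
#' @param size,depth noise dimensions when `model` is a function (defaults
#'   come from the receptive extent otherwise).
#' @return a [ReceptiveField-class]
#' @export
rfByReverseCorrelation <- function(model, stack = 2L, unit = 1L,
                                   nSamples = 1e5, seed = 1L, amplitude = 3,
                                   chunk = 2000L, size = NULL, depth = NULL) {
  if (is.function(model)) {
    stopifnot(!is.null(size), !is.null(depth))
    acc <- array(0, dim = c(size, size, depth))
    rsum <- 0
    done <- 0L; k <- 0L
    while (done < nSamples) {
      k <- k + 1L
      nb <- as.integer(min(chunk, nSamples - done))
      noise <- makeBinaryNoise(nb, size, depth, amplitude,
                               seed = childSeed(seed, k))
      for (s in seq_len(nb)) {
        stim <- noise[, , , s, drop = FALSE]
        dim(stim) <- c(size, size, depth)
        r <- mean(model(stim))
        if (r != 0) { acc <- acc + r * stim; rsum <- rsum + r }
      }
      done <- done + nb
    }
    if (rsum == 0)
      return(new("ReceptiveField", weights = array(NA_real_, dim(acc)),
                 source = "reverse_correlation", unitId = c(NA_integer_,
                                                            NA_integer_),
                 defined = FALSE))
    return(new("ReceptiveField", weights = acc / rsum,
               source = "reverse_correlation",
               unitId = c(NA_integer_, NA_integer_)))
  }
  reverseCorrelationRFs(model, stack, nSamples, seed, amplitude,
                        chunk)[[unit]]
}

#' RF size and polarity switching
#'
#' RF pixels are those in the most recent time step whose absolute weight is
#' at least half the maximum absolute weight in that step; size is their
#' count, and the switch fraction is the fraction of those pixels whose sign
#' differs between the two most recent time steps.
#'
#' @param rf a [ReceptiveField-class] or 3D array (y, x, lag).
#' @return list with `sizePx` and `switchFraction` (NA, flagged via a warning,
#'   for an all-zero slice)
#' @export
rfSizeAndPolarity <- function(rf) {
  w <- if (is(rf, "ReceptiveField")) rf@weights else rf
  nt <- dim(w)[3]
  last <- w[, , nt]
  mx <- max(abs(last))
  if (mx == 0) {
    warning("all-zero RF slice: size and polarity undefined")
    return(list(sizePx = NA_integer_, switchFraction = NA_real_))
  }
  inRf <- abs(last) >= 0.5 * mx
  size <- sum(inRf)
  if (nt < 2L) return(list(sizePx = size, switchFraction = NA_real_))
  prev <- w[, , nt - 1L]
  switched <- sign(last[inRf]) != sign(prev[inRf])
  list(sizePx = as.integer(size), switchFraction = mean(switched))
}

## --- Gabor fitting ----------------------------------------------------------

.gaborEval <- function(p, xg, yg) {
  xr <- (xg - p["x0"]) * cos(p["theta"]) + (yg - p["y0"]) * sin(p["theta"])
  yr <- -(xg - p["x0"]) * sin(p["theta"]) + (yg - p["y0"]) * cos(p["theta"])
  p["A"] * exp(-(xr / (2 * p["sigmaX"]))^2 - (yr / (2 * p["sigmaY"]))^2) *
    cos(2 * pi * p["f"] * xr + p["phi"])
}

# dominant orientation/frequency of a slice from its amplitude spectrum
.fftOrientation <- function(slice) {
  d <- dim(slice)
  sp <- Mod(fft(slice))
  fr <- function(n) c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1) / n
  fy <- matrix(fr(d[1]), d[1], d[2])
  fx <- matrix(fr(d[2]), d[1], d[2], byrow = TRUE)
  sp[1, 1] <- 0
  i <- which.max(sp)
  list(theta = atan2(fy[i], fx[i]) %% pi,
       f = max(sqrt(fx[i]^2 + fy[i]^2), 1 / (2 * max(d))))
}

#' Fit a 2D Gabor to an RF slice
#'
#' Least-squares fit of A * exp(-(x'/(2 sigmaX))^2 - (y'/(2 sigmaY))^2) *
#' cos(2 pi f x' + phi) to the most recent time step of a linear RF, with
#' multiple starts over orientation, frequency and phase (including a start
#' at the slice's spectral peak). The goodness of fit is the pixel-wise
#' Pearson correlation between the slice and the fitted Gabor; units with
#' fit correlation > 0.4 qualify as putative simple cells.
#'
#' @param slice 2D matrix (the most recent time step of an RF), a 3D RF array
#'   (last lag taken), or a [ReceptiveField-class].
#' @param maxIter optimizer iterations per start.
#' @return a [GaborFit-class]; if no start converges, `fitCorrelation` is 0
#'   and `converged` is FALSE
#' @export
fitGabor <- function(slice, maxIter = 100L) {
  if (is(slice, "ReceptiveField")) slice <- slice@weights
  if (length(dim(slice)) == 3L) slice <- slice[, , dim(slice)[3]]
  if (!all(is.finite(slice))) stop("RF slice must be finite")
  d <- dim(slice)
  if (sd(slice) == 0)
    return(new("GaborFit", x0 = NA_real_, y0 = NA_real_, sigmaX = 1,
               sigmaY = 1, theta = 0, f = 0, phi = 0, A = 0,
               fitCorrelation = 0, converged = FALSE))
  xg <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  yg <- matrix(seq_len(d[1]), d[1], d[2])
  wts <- slice^2 / sum(slice^2)
  x0 <- sum(xg * wts); y0 <- sum(yg * wts)
  s0 <- sqrt(max(sum(((xg - x0)^2 + (yg - y0)^2) * wts) / 2, 1))
  A0 <- max(abs(slice))
  est <- .fftOrientation(slice)
  thetas <- unique(c(est$theta, seq(0, 150, by = 30) * pi / 180))
  fs <- unique(c(est$f, 0.05, 0.15))
  phis <- c(0, pi / 2)
  target <- as.numeric(slice)
  best <- NULL
  lower <- c(x0 = -d[2], y0 = -d[1], sigmaX = 0.3, sigmaY = 0.3,
             theta = -2 * pi, f = 0, phi = -2 * pi, A = -5 * A0)
  upper <- c(x0 = 2 * d[2], y0 = 2 * d[1], sigmaX = 4 * max(d),
             sigmaY = 4 * max(d), theta = 4 * pi, f = 0.75, phi = 2 * pi,
             A = 5 * A0)
  for (th in thetas) for (f0 in fs) for (ph in phis) {
    par <- c(x0 = x0, y0 = y0, sigmaX = s0, sigmaY = s0, theta = th, f = f0,
             phi = ph, A = A0)
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par, lower = lower, upper = upper,
                           fn = function(p) {
                             p <- setNames(p, names(par))
                             .gaborEval(p, xg, yg) - target
                           },
                           control = minpack.lm::nls.lm.control(
                             maxiter = maxIter))),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse)
      best <- list(par = setNames(coef(fit), names(par)), sse = sse)
  }
  if (is.null(best))
    return(new("GaborFit", x0 = NA_real_, y0 = NA_real_, sigmaX = 1,
               sigmaY = 1, theta = 0, f = 0, phi = 0, A = 0,
               fitCorrelation = 0, converged = FALSE))
  p <- best$par
  # canonical form: theta in [0, pi) (theta + pi equals phi -> -phi)
  th <- p["theta"] %% (2 * pi)
  if (th >= pi) { th <- th - pi; p["phi"] <- -p["phi"] }
  p["theta"] <- th
  p["phi"] <- ((p["phi"] + pi) %% (2 * pi)) - pi
  fitted <- .gaborEval(p, xg, yg)
  r <- if (sd(fitted) == 0) 0 else cor(as.numeric(fitted), target)
  new("GaborFit", x0 = unname(p["x0"]), y0 = unname(p["y0"]),
      sigmaX = unname(abs(p["sigmaX"])), sigmaY = unname(abs(p["sigmaY"])),
      theta = unname(p["theta"]), f = unname(p["f"]), phi = unname(p["phi"]),
      A = unname(p["A"]), fitCorrelation = r)
}
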