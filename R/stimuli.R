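# Parametric probe stimuli. All stimuli live on the normalized-luminance
# scale of the training clips (gray = 0) and are generated at the stack-1
# input resolution. Time step is 40 ms/frame unless stated otherwise, so a
# temporal frequency tf in Hz corresponds to tf * 0.04 cycles/frame.

.frameDur <- 0.04

#' Full-field drifting sinusoidal grating
#'
#' value(y, x, t) = amplitude * sin(2*pi*sf*(x*cos(d) + y*sin(d))
#'                  - 2*pi*tf*t*dt + phase)
#' where d is the motion direction in degrees (the angle of the spatial
#' frequency vector, measured from +x toward +y, i.e. rightward = 0, downward
#' = 90); the stripes are oriented perpendicular to d and drift along it.
#' Alternates between +/- amplitude about the gray (0) background.
#'
#' @param direction motion direction, degrees in [0, 360).
#' @param sf spatial frequency, cycles/px (must not exceed the 0.5 Nyquist
#'   limit).
#' @param tf temporal frequency, Hz (40 ms frames; 12.5 Hz is the temporal
#'   Nyquist limit).
#' @param size spatial side, px.
#' @param duration frames (default 40, leaving several response cycles after
#'   valid temporal convolution).
#' @param amplitude peak luminance (default 3).
#' @param phase radians.
#' @param frameDur seconds per frame (default 0.04).
#' @return (size, size, duration) array
#' @export
makeGrating <- function(direction, sf, tf, size, duration = 40L,
                        amplitude = 3, phase = 0, frameDur = .frameDur) {
  stopifnot(amplitude > 0)
  if (sf > 0.5 + 1e-12) stop("spatial frequency above the Nyquist limit (0.5 cycles/px)")
  if (tf * frameDur > 0.5 + 1e-12)
    stop("temporal frequency above the Nyquist limit for this frame duration")
  th <- direction * pi / 180
  x <- matrix(seq_len(size) - 1L, size, size, byrow = TRUE)
  y <- matrix(seq_len(size) - 1L, size, size)
  sp <- 2 * pi * sf * (x * cos(th) + y * sin(th))
  out <- array(0, dim = c(size, size, duration))
  for (t in seq_len(duration))
    out[, , t] <- amplitude * sin(sp - 2 * pi * tf * (t - 1L) * frameDur + phase)
  out
}

#' Drifting plaid: two superimposed half-intensity gratings
#'
#' The two component gratings (amplitude 1.5 each by default) move in
#' directions patternDirection +/- separation/2; the net (pattern) motion lies
#' midway between them. Optionally windowed by a circular mask (gray outside).
#'
#' @param patternDirection net motion direction, degrees.
#' @param separation angle between the component motion directions, degrees.
#' @param sf,tf shared spatial/temporal frequency of the components.
#' @param size,duration,phase,frameDur as in [makeGrating()].
#' @param componentAmplitude per-component amplitude (default 1.5).
#' @param maskRadius optional circular-mask radius, px (NULL = full field).
#' @return (size, size, duration) array
#' @export
makePlaid <- function(patternDirection, separation, sf, tf, size,
                      duration = 40L, componentAmplitude = 1.5, phase = 0,
                      maskRadius = NULL, frameDur = .frameDur) {
  g1 <- makeGrating(patternDirection - separation / 2, sf, tf, size, duration,
                    componentAmplitude, phase, frameDur)
  g2 <- makeGrating(patternDirection + separation / 2, sf, tf, size, duration,
                    componentAmplitude, phase, frameDur)
  out <- g1 + g2
  if (!is.null(maskRadius)) {
    cy <- (size + 1) / 2; cx <- (size + 1) / 2
    x <- matrix(seq_len(size), size, size, byrow = TRUE)
    y <- matrix(seq_len(size), size, size)
    mask <- (x - cx)^2 + (y - cy)^2 <= maskRadius^2
    out <- out * array(mask, dim = dim(out))
  }
  out
}

#' Binary noise stimuli
#'
#' Independent equiprobable +/- amplitude values per pixel per frame, used for
#' reverse correlation.
#'
#' @param nSamples number of stimulus samples.
#' @param size spatial side, px.
#' @param depth frames per sample.
#' @param amplitude (default 3).
#' @param seed RNG seed.
#' @return (size, size, depth, nSamples) array
#' @export
makeBinaryNoise <- function(nSamples, size, depth, amplitude = 3, seed = 1L) {
  set.seed(seed)
  n <- size * size * depth * nSamples
  array(amplitude * (2L * (runif(n) < 0.5) - 1L),
        dim = c(size, size, depth, nSamples))
}

#' Blank (gray) stimulus
#'
#' All-zero tensor: gray under the clip-normalization convention. The model's
#' response to it is the bias-driven activity.
#'
#' @param size spatial side, px.
#' @param duration frames.
#' @return (size, size, duration) array of zeros
#' @export
makeBlank <- function(size, duration = 40L) {
  array(0, dim = c(size, size, duration))
}
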