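#' Construct a ClipSet
#'
#' Low-level constructor; most users will obtain ClipSets from
#' [preprocessVideo()], [synthMovies()], [panAugment()] or [frameShuffle()].
#'
#' @param clips list of 3D (y, x, t) arrays of identical dimension.
#' @param split character vector of "train"/"validation" labels, one per clip.
#' @param frameRate frames per second (default 25, the source material rate).
#' @param provenance one of "natural", "synthetic", "panned",
#'   "frame_shuffled".
#' @param seed integer seed recorded for provenance (NA if deterministic).
#' @return a [ClipSet-class]
#' @export
clipSet <- function(clips, split = rep("train", length(clips)),
                    frameRate = 25, provenance = "natural",
                    seed = NA_integer_) {
  new("ClipSet", clips = clips, split = split, frameRate = frameRate,
      provenance = provenance, seed = as.integer(seed))
}

#' Normalize a clip to zero mean and unit standard deviation
#'
#' @param x 3D array.
#' @return normalized array
#' @export
normalizeClip <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop("degenerate clip: zero variance (constant frames); cannot normalize")
  (x - mean(x)) / s
}

#' Assign a train/validation split at clip granularity
#'
#' @param object a ClipSet.
#' @param trainFraction fraction of clips assigned to training (default 0.9,
#'   matching a ~1305/~145 clip partition).
#' @param seed RNG seed fixing the assignment.
#' @return the ClipSet with its split relabeled
#' @export
splitClips <- function(object, trainFraction = 0.9, seed = 1L) {
  n <- length(object@clips)
  nTrain <- round(trainFraction * n)
  set.seed(seed)
  train <- sample.int(n, nTrain)
  split <- rep("validation", n)
  split[train] <- "train"
  object@split <- split
  validObject(object)
  object
}

#' Cut raw grayscale footage into normalized training clips
#'
#' Center-crops each frame to a square along its longest dimension,
#' downsamples with bilinear interpolation to `targetSide` x `targetSide`
#' pixels, cuts the sequence into non-overlapping clips of `clipLen` frames
#' (dropping any trailing remainder), and normalizes each clip by subtracting
#' its own mean and dividing by its own standard deviation. Constant
#' (zero-variance) clips are rejected with a diagnostic rather than divided by
#' zero.
#'
#' @param frames a 3D (y, x, t) array, a list of equal-sized matrices, or a
#'   directory containing PNG/TIFF frames (read in lexicographic order).
#' @param targetSide spatial side length after downsampling, px (default 181).
#' @param clipLen frames per clip (default 20, i.e. 800 ms at 25 fps).
#' @param frameRate frames per second of the footage.
#' @param trainFraction,seed train/validation split parameters (clip
#'   granularity).
#' @return a [ClipSet-class]
#' @export
preprocessVideo <- function(frames, targetSide = 181L, clipLen = 20L,
                            frameRate = 25, trainFraction = 0.9, seed = 1L) {
  if (clipLen < 2L) stop("clipLen must be at least 2")
  frames <- .readFrames(frames)
  d <- dim(frames)
  side <- min(d[1], d[2])
  y0 <- floor((d[1] - side) / 2)
  x0 <- floor((d[2] - side) / 2)
  frames <- frames[y0 + seq_len(side), x0 + seq_len(side), , drop = FALSE]
  if (side != targetSide) frames <- .bilinearResize(frames, targetSide)
  nClips <- floor(d[3] / clipLen)
  if (nClips < 1L) stop("footage shorter than one clip")
  out <- vector("list", nClips)
  keep <- logical(nClips)
  for (i in seq_len(nClips)) {
    cl <- frames[, , (i - 1L) * clipLen + seq_len(clipLen), drop = FALSE]
    if (sd(cl) == 0) {
      warning(sprintf("clip %d rejected: zero variance (constant frames)", i))
      next
    }
    out[[i]] <- normalizeClip(cl)
    keep[i] <- TRUE
  }
  if (!any(keep)) stop("no usable clips: all had zero variance")
  cs <- clipSet(out[keep], frameRate = frameRate, provenance = "natural")
  splitClips(cs, trainFraction, seed)
}

.readFrames <- function(frames) {
  if (is.character(frames) && length(frames) == 1L && dir.exists(frames)) {
    files <- sort(list.files(frames, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) stop("no PNG/TIFF frames found in directory")
    rd <- function(f) {
      img <- if (grepl("png$", f, ignore.case = TRUE)) {
        if (!requireNamespace("png", quietly = TRUE))
          stop("reading PNG frames requires the 'png' package")
        png::readPNG(f)
      } else {
        if (!requireNamespace("tiff", quietly = TRUE))
          stop("reading TIFF frames requires the 'tiff' package")
        tiff::readTIFF(f)
      }
      if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3, dim(img)[3]),
                                                   drop = FALSE], c(1, 2), mean)
      img
    }
    mats <- lapply(files, rd)
    frames <- mats
  }
  if (is.list(frames)) {
    d <- dim(frames[[1]])
    if (!all(vapply(frames, function(m) identical(dim(m), d), logical(1))))
      stop("all frames must share one resolution")
    frames <- array(unlist(frames), dim = c(d, length(frames)))
  }
  if (length(dim(frames)) != 3L) stop("frames must form a (y, x, t) array")
  frames
}

# bilinear spatial resize of a (y, x, t) stack; EBImage carries the
# interpolation when available, with a plain-R fallback
.bilinearResize <- function(frames, side) {
  d <- dim(frames)
  if (requireNamespace("EBImage", quietly = TRUE)) {
    out <- array(0, dim = c(side, side, d[3]))
    for (t in seq_len(d[3]))
      out[, , t] <- EBImage::resize(frames[, , t], w = side, h = side)
    return(out)
  }
  # map output pixel centers onto input pixel centers and interpolate
  src <- function(n, m) pmin(pmax((seq_len(m) - 0.5) * n / m + 0.5, 1), n)
  ys <- src(d[1], side); xs <- src(d[2], side)
  y0 <- pmin(floor(ys), d[1] - 1L); x0 <- pmin(floor(xs), d[2] - 1L)
  wy <- ys - y0; wx <- xs - x0
  out <- array(0, dim = c(side, side, d[3]))
  for (t in seq_len(d[3])) {
    f <- frames[, , t]
    out[, , t] <- outer(1 - wy, 1 - wx) * f[y0, x0] +
      outer(1 - wy, wx) * f[y0, x0 + 1L] +
      outer(wy, 1 - wx) * f[y0 + 1L, x0] +
      outer(wy, wx) * f[y0 + 1L, x0 + 1L]
  }
  out
}

#' Augment a ClipSet with horizontal panning
#'
#' For every signed shift, adds a copy of each clip in which frame t (0-based)
#' is translated horizontally by shift*t pixels with wrap-around (circular)
#' boundaries, then re-normalized. With the standard shifts (+/-1, +/-2, +/-3
#' px/frame) the clip count is multiplied by 7.
#'
#' @param object a ClipSet.
#' @param shifts integer vector of signed px/frame shifts.
#' @return a ClipSet containing the originals followed by the panned copies
#' @export
panAugment <- function(object, shifts = c(-3L, -2L, -1L, 1L, 2L, 3L)) {
  d <- dim(object@clips[[1]])
  if (any(abs(shifts) * d[3] >= d[2]))
    stop("|shift| * clip length reaches the frame width")
  out <- object@clips
  split <- object@split
  for (s in shifts) {
    panned <- lapply(object@clips, function(cl) {
      p <- cl
      if (s != 0) for (t in seq_len(d[3])[-1]) {
        k <- (s * (t - 1L)) %% d[2]
        if (k != 0) p[, , t] <- cl[, c((d[2] - k + 1L):d[2], 1L:(d[2] - k)), t]
      }
      normalizeClip(p)
    })
    out <- c(out, panned)
    split <- c(split, object@split)
  }
  new("ClipSet", clips = out, split = split, frameRate = object@frameRate,
      provenance = "panned", seed = object@seed)
}

#' Shuffle the frame order within each clip
#'
#' Draws an independent uniform permutation of the frames of every clip,
#' destroying temporal structure while preserving each clip's multiset of
#' frames exactly.
#'
#' @param object a ClipSet.
#' @param seed RNG seed fixing the permutation stream.
#' @return a ClipSet with provenance "frame_shuffled"
#' @export
frameShuffle <- function(object, seed = 1L) {
  set.seed(seed)
  nt <- dim(object@clips[[1]])[3]
  shuffled <- lapply(object@clips, function(cl) cl[, , sample.int(nt)])
  new("ClipSet", clips = shuffled, split = object@split,
      frameRate = object@frameRate, provenance = "frame_shuffled",
      seed = as.integer(seed))
}

#' Synthesize translating-texture movie clips
#'
#' Stand-in for natural wildlife footage: each clip is a random-phase texture
#' whose radial amplitude spectrum falls as frequency^(-spectrumExponent)
#' (the approximately 1/f statistics of natural images), rigidly translated at
#' a per-clip velocity. A fraction of clips is still (zero velocity),
#' emulating footage from a stationary camera; the rest drift in a uniformly
#' random direction at a speed drawn uniformly up to `velocityRange`.
#' Translation is circular (the texture lives on a torus), so clips need no
#' margin cropping. Each clip is normalized to zero mean, unit sd.
#'
#' @param nClips number of clips.
#' @param velocityRange maximum drift speed, px/frame (default 3, matching the
#'   strongest panning augmentation used for natural footage).
#' @param spectrumExponent amplitude-spectrum exponent (default 1; power falls
#'   as f^-2).
#' @param seed RNG seed.
#' @param side spatial side, px (default 181).
#' @param clipLen frames per clip (default 20).
#' @param stillFraction fraction of zero-velocity clips (default 0.2).
#' @param trainFraction train split fraction (default 0.9).
#' @return a [ClipSet-class] with provenance "synthetic"; the per-clip
#'   velocities are attached as attribute "velocities" (nClips x 2 matrix of
#'   (vx, vy))
#' @export
synthMovies <- function(nClips, velocityRange = 3, spectrumExponent = 1,
                        seed = 1L, side = 181L, clipLen = 20L,
                        stillFraction = 0.2, trainFraction = 0.9) {
  stopifnot(nClips >= 1, is.finite(velocityRange))
  set.seed(seed)
  # radial frequency grid (cycles/px) on the FFT torus
  fr <- c(0:floor(side / 2), -(ceiling(side / 2) - 1):-1) / side
  fx <- matrix(fr, side, side, byrow = TRUE)
  fy <- matrix(fr, side, side)
  rad <- sqrt(fx^2 + fy^2)
  amp <- ifelse(rad > 0, rad^(-spectrumExponent), 0)
  clips <- vector("list", nClips)
  vel <- matrix(0, nClips, 2, dimnames = list(NULL, c("vx", "vy")))
  for (n in seq_len(nClips)) {
    if (runif(1) >= stillFraction) {
      ang <- runif(1, 0, 2 * pi)
      spd <- runif(1, 0.5, max(0.5, velocityRange))
      vel[n, ] <- spd * c(cos(ang), sin(ang))
    }
    white <- matrix(rnorm(side * side), side, side)
    spec <- fft(white) * amp
    cl <- array(0, dim = c(side, side, clipLen))
    for (t in seq_len(clipLen)) {
      ramp <- exp(-2i * pi * ((t - 1) * (vel[n, 1] * fx + vel[n, 2] * fy)))
      cl[, , t] <- Re(fft(spec * ramp, inverse = TRUE)) / side^2
    }
    clips[[n]] <- normalizeClip(cl)
  }
  cs <- clipSet(clips, provenance = "synthetic", seed = seed)
  cs <- splitClips(cs, trainFraction, seed = childSeed(seed, 1L))
  attr(cs, "velocities") <- vel
  cs
}

#' Save / load a ClipSet
#'
#' Serializes the clip array together with its manifest (split, provenance,
#' frame rate, seed).
#'
#' @param object a ClipSet.
#' @param path file path.
#' @return `readClipSet` returns the ClipSet
#' @export
saveClipSet <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname saveClipSet
#' @export
readClipSet <- function(path) {
  obj <- readRDS(path)
  stopifnot(is(obj, "ClipSet"))
  validObject(obj)
  obj
}
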