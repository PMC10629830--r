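test_that("preprocessing cuts, crops, downsamples and normalizes per clip", {
  set.seed(1)
  frames <- array(rnorm(40 * 50 * 300), c(40, 50, 300))
  cs <- preprocessVideo(frames, targetSide = 20L, clipLen = 20L)
  expect_equal(length(cs), 15L)
  expect_equal(dim(clips(cs)[[1]]), c(20L, 20L, 20L))
  for (cl in clips(cs)) {
    expect_lt(abs(mean(cl)), 1e-6)
    expect_lt(abs(sd(cl) - 1), 1e-6)
  }
  # split is disjoint and assigned at clip granularity
  expect_equal(sort(unique(clipSplit(cs))), c("train", "validation"))
  expect_equal(sum(clipSplit(cs) == "train"), round(0.9 * 15))
})

test_that("normalization is idempotent and affine-invariant", {
  set.seed(2)
  x <- array(rnorm(10 * 10 * 20), c(10, 10, 20))
  z <- normalizeClip(x)
  expect_lt(max(abs(normalizeClip(z) - z)), 1e-6)
  expect_lt(max(abs(normalizeClip(3.7 * x + 11) - z)), 1e-9)
})

test_that("zero-variance clips are rejected, not divided by zero", {
  expect_error(normalizeClip(array(0.5, c(5, 5, 20))), "zero variance")
  frames <- array(1, c(10, 10, 20))
  expect_error(suppressWarnings(preprocessVideo(frames, targetSide = 10L)),
               "zero variance")
  # mixed footage: constant clip dropped with a diagnostic, the rest kept
  set.seed(3)
  frames <- array(rnorm(10 * 10 * 40), c(10, 10, 40))
  frames[, , 21:40] <- 0
  expect_warning(cs <- preprocessVideo(frames, targetSide = 10L),
                 "zero variance")
  expect_equal(length(cs), 1L)
})

test_that("panning multiplies clips, translates with wrap-around, renormalizes", {
  set.seed(4)
  cs <- clipSet(lapply(1:10, function(i) {
    normalizeClip(array(rnorm(12 * 30 * 5), c(12, 30, 5)))
  }))
  aug <- panAugment(cs, shifts = c(-3, -2, -1, 1, 2, 3))
  expect_equal(length(aug), 70L)

  one <- clipSet(list(normalizeClip(array(rnorm(12 * 30 * 5), c(12, 30, 5)))))
  shifted <- clips(panAugment(one, shifts = 1L))[[2]]
  src <- clips(one)[[1]]
  # column c of frame t equals column c - t of the source (0-based t, interior)
  for (t in 1:4) {
    expect_equal(shifted[, (t + 2):30, t + 1],
                 src[, (t + 2):30 - t, t + 1], tolerance = 1e-12)
  }
  ident <- panAugment(one, shifts = 0L)
  expect_equal(clips(ident)[[2]], clips(one)[[1]])
  expect_error(panAugment(one, shifts = 6L), "frame width")
})

test_that("frame shuffle preserves content, is deterministic, kills order", {
  set.seed(5)
  cs <- tinyClips(n = 6, side = 16L)
  sh1 <- frameShuffle(cs, seed = 99)
  sh2 <- frameShuffle(cs, seed = 99)
  expect_identical(clips(sh1), clips(sh2))
  # multiset of frames preserved exactly
  frameKey <- function(cl) sort(apply(cl, 3, function(f) sum(f * seq_along(f))))
  for (i in seq_along(clips(cs)))
    expect_equal(frameKey(clips(cs)[[i]]), frameKey(clips(sh1)[[i]]))
  # adjacent-frame correlation drops on translating clips
  adjCor <- function(cl) {
    nt <- dim(cl)[3]
    mean(sapply(1:(nt - 1), function(t)
      cor(as.numeric(cl[, , t]), as.numeric(cl[, , t + 1]))))
  }
  expect_lt(mean(sapply(clips(sh1), adjCor)),
            mean(sapply(clips(cs), adjCor)))
})

test_that("shuffled frame positions match uniform-permutation statistics", {
  # oracle: mean |new index - old index| under a uniform permutation of n,
  # computed by exhaustive expectation E|i - j| over the uniform assignment
  n <- 20
  oracle <- mean(abs(outer(1:n, 1:n, "-")))
  cl <- array(seq_len(4 * 4 * n), c(4, 4, n)) # frame t has known signature
  cs <- clipSet(lapply(1:40, function(i) cl))
  disp <- c()
  for (s in 1:25) {
    sh <- frameShuffle(cs, seed = s)
    disp <- c(disp, sapply(clips(sh), function(x) {
      newPos <- match(x[1, 1, ], cl[1, 1, ])
      mean(abs(newPos - seq_len(n)))
    }))
  }
  expect_lt(abs(mean(disp) - oracle), 0.25)
})

test_that("synthetic movies translate rigidly with the requested statistics", {
  cs <- synthMovies(6, side = 32L, seed = 21, stillFraction = 0)
  vel <- attr(cs, "velocities")
  # integer-velocity clip: cross-correlation peak between adjacent frames at
  # the velocity displacement (brute-force oracle over circular shifts)
  cs2 <- synthMovies(1, side = 32L, seed = 33, stillFraction = 0)
  cl <- clips(cs2)[[1]]
  v <- attr(cs2, "velocities")[1, ]
  xc <- function(a, b, dy, dx) {
    n <- dim(a)[1]
    bs <- b[((seq_len(n) - 1 - dy) %% n) + 1, ((seq_len(n) - 1 - dx) %% n) + 1]
    sum(a * bs)
  }
  # round the (continuous) velocity: peak should sit at the nearest lattice
  # point of the per-frame displacement
  best <- c(NA, NA); bv <- -Inf
  for (dy in -4:4) for (dx in -4:4) {
    val <- xc(cl[, , 2], cl[, , 1], dy, dx)
    if (val > bv) { bv <- val; best <- c(dy, dx) }
  }
  expect_equal(best[2], round(v["vx"]), ignore_attr = TRUE, tolerance = 1)
  expect_equal(best[1], round(v["vy"]), ignore_attr = TRUE, tolerance = 1)

  # zero velocity: all frames identical (up to normalization they already are)
  cs0 <- synthMovies(3, side = 24L, seed = 5, stillFraction = 1)
  for (cl in clips(cs0))
    expect_lt(max(abs(cl[, , 1] - cl[, , 10])), 1e-10)

  # radial amplitude spectrum ~ f^-1 means log-log power slope ~ -2
  cs1 <- synthMovies(8, side = 64L, seed = 8, spectrumExponent = 1)
  slopes <- sapply(clips(cs1), function(cl) {
    sp <- Mod(fft(cl[, , 1]))^2
    fr <- c(0:32, -31:-1) / 64
    rad <- sqrt(outer(fr^2, fr^2, "+"))
    sel <- rad > 0.03 & rad < 0.4
    coef(lm.fit(cbind(1, log(rad[sel])), log(sp[sel])))[2]
  })
  expect_lt(abs(mean(slopes) + 2), 0.35)
})

test_that("frame directories of PNGs are read in order", {
  dir <- tempfile("frames")
  dir.create(dir)
  set.seed(6)
  vals <- seq(0, 1, length.out = 20)
  for (t in 1:20) {
    img <- matrix(vals[t] * seq(0, 1, length.out = 256), 16, 16)
    png::writePNG(img, file.path(dir, sprintf("frame_%02d.png", t)))
  }
  cs <- preprocessVideo(dir, targetSide = 16L, clipLen = 20L)
  expect_equal(length(cs), 1L)
  cl <- clips(cs)[[1]]
  # frame order preserved: later frames are brighter in the source, so the
  # normalized clip increases monotonically at a fixed pixel
  expect_true(all(diff(cl[8, 8, ]) > 0))
})

test_that("clip sets round-trip through save/read", {
  cs <- tinyClips(n = 3, side = 12L)
  path <- tempfile(fileext = ".rds")
  saveClipSet(cs, path)
  expect_identical(clips(readClipSet(path)), clips(cs))
})
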