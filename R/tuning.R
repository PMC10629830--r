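# Grating/plaid tuning metrics and the unit-characterization pipeline.

#' Responses of every unit to a grid of drifting gratings
#'
#' Presents each (direction, sf, tf) grating once and records the activity
#' trace of the spatially central hidden unit of every convolutional channel
#' in every stack.
#'
#' @param model a [HierarchicalModel-class].
#' @param size stimulus side, px (the stack-1 input resolution; any size
#'   admitting valid convolution through the probed stacks).
#' @param directions motion directions, degrees (default 0-355 step 5).
#' @param sfs spatial frequencies, cycles/px (default 8 log steps, 0.02-0.4).
#' @param tfs temporal frequencies, Hz (default 0.625, 1.25, 2.5, 5, 12.5).
#' @param duration frames.
#' @param amplitude grating amplitude (default 3).
#' @param upTo highest stack to record.
#' @return list with `grid` (data.frame direction/sf/tf), `traces` (per stack,
#'   array nStim x J x T_h), `blank` (per stack, matrix J x T_h), and the
#'   stimulus parameters
#' @export
gratingResponses <- function(model, size, directions = seq(0, 355, by = 5),
                             sfs = exp(seq(log(0.02), log(0.4), length.out = 8)),
                             tfs = c(0.625, 1.25, 2.5, 5, 12.5),
                             duration = 40L, amplitude = 3,
                             upTo = stackCount(model)) {
  grid <- expand.grid(direction = directions, sf = sfs, tf = tfs,
                      KEEP.OUT.ATTRS = FALSE)
  nStim <- nrow(grid)
  traces <- vector("list", upTo)
  blankH <- forwardHierarchy(model, makeBlank(size, duration), upTo = upTo)
  blank <- lapply(blankH, function(H) {
    d <- dim(H)
    t(H[ceiling(d[1] / 2), ceiling(d[2] / 2), , , drop = TRUE])
  })
  for (z in seq_len(upTo)) {
    d <- dim(blankH[[z]])
    traces[[z]] <- array(0, dim = c(nStim, d[4], d[3]))
  }
  for (s in seq_len(nStim)) {
    stim <- makeGrating(grid$direction[s], grid$sf[s], grid$tf[s], size,
                        duration, amplitude)
    Hs <- forwardHierarchy(model, stim, upTo = upTo)
    for (z in seq_len(upTo)) {
      d <- dim(Hs[[z]])
      traces[[z]][s, , ] <-
        t(Hs[[z]][ceiling(d[1] / 2), ceiling(d[2] / 2), , ])
    }
  }
  list(grid = grid, traces = traces, blank = blank, size = size,
       duration = duration, amplitude = amplitude)
}

#' Optimal grating of a unit
#'
#' The grid point maximizing the unit's mean response over time; ties broken
#' by lowest spatial frequency, then lowest temporal frequency, then lowest
#' direction.
#'
#' @param responses output of [gratingResponses()].
#' @param stack,unit which unit.
#' @return list with `params` (direction, sf, tf), `response` (mean over
#'   time), `trace`, and `unresponsive` flag (all responses zero)
#' @export
findOptimalGrating <- function(responses, stack, unit) {
  mr <- rowMeans(responses$traces[[stack]][, unit, , drop = FALSE][, 1, ])
  grid <- responses$grid
  best <- max(mr)
  cand <- which(mr >= best - 1e-12)
  cand <- cand[order(grid$sf[cand], grid$tf[cand], grid$direction[cand])]
  i <- cand[1]
  list(params = c(direction = grid$direction[i], sf = grid$sf[i],
                  tf = grid$tf[i]),
       response = mr[i],
       trace = responses$traces[[stack]][i, unit, ],
       index = i,
       unresponsive = best == 0)
}

#' Exclude weakly responding units
#'
#' @param responses vector of per-unit mean responses (e.g. at the optimal
#'   grating).
#' @param thresholdFraction units responding below this fraction of the
#'   population maximum are excluded (1% for the per-stack tuning protocol;
#'   0.1% for population-wide pooling).
#' @return logical keep flags
#' @export
unitExclusion <- function(responses, thresholdFraction = 0.01) {
  responses >= thresholdFraction * max(responses)
}

#' Circular variance of a direction tuning curve
#'
#' CV = 1 - |sum_q r_q exp(2 i theta_q)| / sum_q r_q, with the angle doubling
#' that makes opposite motion directions reinforce; 0 is perfectly
#' orientation-tuned, 1 untuned.
#'
#' @param rq mean responses over time on the direction grid.
#' @param directions directions, degrees (equally spaced over 0-360,
#'   conventionally in 5 degree steps).
#' @return CV in [0, 1]; NA (with a warning) when the responses sum to zero
#' @export
circularVariance <- function(rq, directions) {
  s <- sum(rq)
  if (s == 0) { warning("zero summed response: CV undefined"); return(NA_real_) }
  th <- directions * pi / 180
  1 - sqrt(sum(rq * sin(2 * th))^2 + sum(rq * cos(2 * th))^2) / s
}

# circular smoothing with a Hanning kernel of given half-width at half-height
.hanningSmooth <- function(rq, stepDeg, hwhhDeg = 13.5) {
  L <- 2 * hwhhDeg
  kOff <- seq(-floor(L / stepDeg), floor(L / stepDeg))
  w <- 0.5 * (1 + cos(pi * kOff * stepDeg / L))
  w <- w / sum(w)
  n <- length(rq)
  out <- numeric(n)
  for (i in seq_len(n))
    out[i] <- sum(w * rq[((i - 1 + kOff) %% n) + 1])
  out
}

#' Orientation bandwidth of a direction tuning curve
#'
#' The curve is smoothed with a Hanning window (half-width at half-height
#' 13.5 degrees); the two directions nearest the peak where the smoothed
#' response falls to `criterion` (default 70.7%) of the peak are found by
#' linear interpolation, and the bandwidth is half their angular difference,
#' capped at 180 degrees (also returned when no crossing exists).
#'
#' @param rq responses on the direction grid.
#' @param directions degrees, equally spaced over 0-360.
#' @param criterion crossing level relative to peak (1/sqrt(2) by default;
#'   0.5 gives the half-amplitude convention).
#' @return bandwidth in degrees, <= 180
#' @export
orientationBandwidth <- function(rq, directions, criterion = 1 / sqrt(2)) {
  step <- diff(directions[1:2])
  sm <- .hanningSmooth(rq, step)
  n <- length(sm)
  pk <- which.max(sm)
  level <- criterion * sm[pk]
  cross <- function(dir) { # dir = +1 rightward, -1 leftward
    for (k in seq_len(n - 1)) {
      i0 <- ((pk - 1 + dir * (k - 1)) %% n) + 1
      i1 <- ((pk - 1 + dir * k) %% n) + 1
      if (sm[i1] <= level && sm[i0] > level) {
        frac <- (sm[i0] - level) / (sm[i0] - sm[i1])
        return((k - 1 + frac) * step)
      }
    }
    NA_real_
  }
  right <- cross(1); left <- cross(-1)
  if (is.na(right) || is.na(left)) return(180)
  min((right + left) / 2, 180)
}

#' Modulation ratio F1/F0 of a response trace
#'
#' F0 is the time-mean response; F1 the amplitude of the least-squares
#' sinusoid at the stimulus temporal frequency (fit rather than FFT bin, so
#' non-integer cycle counts are tolerated). MR > 1 indicates simple-cell-like
#' modulated responses; MR < 1 complex-cell-like.
#'
#' @param trace response over time (one value per frame).
#' @param cyclesPerFrame stimulus temporal frequency in cycles/frame
#'   (tf in Hz times the frame duration).
#' @return list with `F0`, `F1`, `MR` (MR is NA, flagged by a warning, when
#'   F0 = 0)
#' @export
modulationRatio <- function(trace, cyclesPerFrame) {
  t <- seq_along(trace) - 1
  X <- cbind(sin(2 * pi * cyclesPerFrame * t), cos(2 * pi * cyclesPerFrame * t))
  fit <- lm.fit(cbind(1, X), trace)
  F1 <- sqrt(sum(coef(fit)[2:3]^2))
  F0 <- mean(trace)
  if (F0 == 0) {
    warning("zero mean response: modulation ratio undefined")
    return(list(F0 = 0, F1 = F1, MR = NA_real_))
  }
  list(F0 = F0, F1 = F1, MR = F1 / F0)
}

#' Direction selectivity indices
#'
#' DSI1 = (rp - rnp) / (rp + rnp); DSI2 = (rp - rnp) / rp;
#' DSI3 = 1 - (rnp - rnull) / (rp - rnull). rp is the peak of the direction
#' tuning curve, rnp the response at the opposite direction, rnull the
#' response to a blank. DSI3 can exceed 1 when the non-preferred response
#' falls below the blank response.
#'
#' @param rq responses on the direction grid.
#' @param directions degrees.
#' @param rnull blank response.
#' @return list with `dsi1`, `dsi2`, `dsi3`, `preferredDirection` (undefined
#'   indices are NA)
#' @export
directionSelectivity <- function(rq, directions, rnull = 0) {
  ip <- which.max(rq)
  rp <- rq[ip]
  opp <- (directions[ip] + 180) %% 360
  inp <- which.min(pmin(abs(directions - opp), 360 - abs(directions - opp)))
  rnp <- rq[inp]
  list(dsi1 = if (rp + rnp == 0) NA_real_ else (rp - rnp) / (rp + rnp),
       dsi2 = if (rp == 0) NA_real_ else (rp - rnp) / rp,
       dsi3 = if (rp == rnull) NA_real_ else 1 - (rnp - rnull) / (rp - rnull),
       preferredDirection = directions[ip])
}

#' Classify a unit as simple, complex or non-oriented
#'
#' Simple: Gabor fit correlation > 0.4, circular variance < 0.9 and
#' modulation ratio > 1. Complex: circular variance < 0.9 and modulation
#' ratio < 1. Anything else responsive is non-oriented; units with undefined
#' CV or MR are excluded. Direction-tuned flag: (simple or complex) with
#' DSI1 > 0.5.
#'
#' @param cv circular variance.
#' @param mr modulation ratio.
#' @param fitCorr Gabor fit correlation (NA treated as non-qualifying).
#' @param dsi1 direction selectivity index 1.
#' @param excluded TRUE when the unit failed the response-strength criterion.
#' @return list with `label` and `directionTuned`
#' @export
classifyUnit <- function(cv, mr, fitCorr = NA, dsi1 = NA, excluded = FALSE) {
  if (excluded || is.na(cv) || is.na(mr))
    return(list(label = "excluded", directionTuned = FALSE))
  label <- if (!is.na(fitCorr) && fitCorr > 0.4 && cv < 0.9 && mr > 1) "simple"
           else if (cv < 0.9 && mr < 1) "complex"
           else "non_oriented"
  list(label = label,
       directionTuned = label %in% c("simple", "complex") &&
         !is.na(dsi1) && dsi1 > 0.5)
}

#' Characterize every unit of a model with drifting gratings
#'
#' Runs the full grating protocol: optimal-grating search over the grid,
#' per-stack exclusion of weak responders (mean response < 1% of the stack's
#' maximum), direction tuning at the optimal spatial/temporal frequency,
#' circular variance, orientation bandwidth, modulation ratio, direction
#' selectivity, Gabor fit of the linear RF (stack-1 kernels directly, deeper
#' stacks by reverse correlation) and simple/complex/non-oriented
#' classification.
#'
#' @param model a [HierarchicalModel-class].
#' @param size stimulus side, px.
#' @param directions,sfs,tfs,duration,amplitude grating grid (see
#'   [gratingResponses()]).
#' @param rcSamples binary-noise samples for reverse-correlation RFs of
#'   stacks >= 2.
#' @param seed RNG seed for reverse correlation.
#' @param exclusionFraction response-strength threshold (default 0.01).
#' @param responses optionally a precomputed [gratingResponses()] result.
#' @return data.frame, one row per (stack, unit), with tuning measures and
#'   class label
#' @export
characterizeModel <- function(model, size, directions = seq(0, 355, by = 5),
                              sfs = exp(seq(log(0.02), log(0.4),
                                            length.out = 8)),
                              tfs = c(0.625, 1.25, 2.5, 5, 12.5),
                              duration = 40L, amplitude = 3,
                              rcSamples = 2e4, seed = 1L,
                              exclusionFraction = 0.01, responses = NULL) {
  if (is.null(responses))
    responses <- gratingResponses(model, size, directions, sfs, tfs, duration,
                                  amplitude)
  grid <- responses$grid
  rows <- list()
  for (z in seq_along(responses$traces)) {
    J <- dim(responses$traces[[z]])[2]
    opt <- lapply(seq_len(J), function(j) findOptimalGrating(responses, z, j))
    optResp <- vapply(opt, `[[`, numeric(1), "response")
    keep <- unitExclusion(optResp, exclusionFraction) &
      !vapply(opt, `[[`, logical(1), "unresponsive")
    rfs <- NULL
    if (z == 1L) {
      rfs <- lapply(seq_len(J), function(j) rfFromWeights(model, j))
    } else if (any(keep)) {
      rfs <- reverseCorrelationRFs(model, z, nSamples = rcSamples,
                                   seed = childSeed(seed, z))
    }
    for (j in seq_len(J)) {
      o <- opt[[j]]
      rnull <- mean(responses$blank[[z]][j, ])
      if (!keep[j]) {
        rows[[length(rows) + 1L]] <- data.frame(
          stack = z, unit = j, direction = NA, sf = NA, tf = NA,
          response = optResp[j], F0 = NA, F1 = NA, MR = NA, CV = NA,
          bandwidth = NA, dsi1 = NA, dsi2 = NA, dsi3 = NA, rnull = rnull,
          fitCorrelation = NA, label = "excluded", directionTuned = FALSE)
        next
      }
      sel <- grid$sf == o$params["sf"] & grid$tf == o$params["tf"]
      ord <- order(grid$direction[sel])
      rq <- rowMeans(responses$traces[[z]][sel, j, , drop = FALSE][, 1, ,
                                                                   drop = FALSE])
      dim(rq) <- NULL
      rq <- rq[ord]
      dirs <- sort(grid$direction[sel])
      cv <- suppressWarnings(circularVariance(rq, dirs))
      bw <- orientationBandwidth(rq, dirs)
      mrr <- suppressWarnings(
        modulationRatio(o$trace, o$params["tf"] * .frameDur))
      ds <- directionSelectivity(rq, dirs, rnull)
      fitCorr <- NA_real_
      if (!is.null(rfs) && rfs[[j]]@defined)
        fitCorr <- fitCorrelation(fitGabor(rfs[[j]]))
      cls <- classifyUnit(cv, mrr$MR, fitCorr, ds$dsi1)
      rows[[length(rows) + 1L]] <- data.frame(
        stack = z, unit = j, direction = o$params[["direction"]],
        sf = o$params[["sf"]], tf = o$params[["tf"]], response = optResp[j],
        F0 = mrr$F0, F1 = mrr$F1, MR = mrr$MR, CV = cv, bandwidth = bw,
        dsi1 = ds$dsi1, dsi2 = ds$dsi2, dsi3 = ds$dsi3, rnull = rnull,
        fitCorrelation = fitCorr, label = cls$label,
        directionTuned = cls$directionTuned)
    }
  }
  do.call(rbind, rows)
}

## --- plaid analysis ---------------------------------------------------------

# partial correlations of an observed tuning curve with the pattern and
# component predictions derived from the grating tuning curve
.plaidPartialCorrelations <- function(observed, pattern, component) {
  if (sd(observed) == 0 || sd(pattern) == 0 || sd(component) == 0)
    return(list(Rp = NA_real_, Rc = NA_real_))
  rop <- cor(observed, pattern)
  roc <- cor(observed, component)
  rpc <- cor(pattern, component)
  list(Rp = (rop - roc * rpc) / sqrt((1 - roc^2) * (1 - rpc^2)),
       Rc = (roc - rop * rpc) / sqrt((1 - rop^2) * (1 - rpc^2)))
}

# count local maxima of a smoothed circular tuning curve above half its peak
.peakCount <- function(rq, stepDeg) {
  sm <- .hanningSmooth(rq, stepDeg)
  n <- length(sm)
  thr <- 0.5 * max(sm)
  sum(vapply(seq_len(n), function(i) {
    l <- sm[((i - 2) %% n) + 1]; r <- sm[(i %% n) + 1]
    sm[i] > thr && sm[i] >= l && sm[i] > r
  }, logical(1)))
}

#' Pattern/component analysis with drifting plaids
#'
#' Measures direction tuning (time-mean response vs pattern direction) for
#' plaids at each component separation, along with the unit's grating
#' direction tuning at the same spatial/temporal frequency. Classification
#' follows the standard partial-correlation construction: the observed plaid
#' tuning is compared with the pattern prediction (the grating tuning itself)
#' and the component prediction (the grating tuning replicated at the two
#' component directions); Fisher-z statistics z = atanh(R) * sqrt(n - 3) are
#' compared and a unit is pattern- (or component-) classified when its z
#' exceeds max(other z, 0) by 1.28 (about 90% confidence). A descriptive peak
#' count of the plaid tuning curve is also returned (component-selective
#' units show two peaks, pattern-selective units one).
#'
#' @param model a [HierarchicalModel-class] or a plain response function
#'   (stimulus array -> trace).
#' @param stack,unit which unit (ignored for a function).
#' @param sf,tf plaid spatial/temporal frequency (use the unit's optimal
#'   grating values).
#' @param size,duration stimulus geometry.
#' @param separations component separations, degrees.
#' @param directions pattern-direction grid, degrees.
#' @param maskRadius optional circular mask radius.
#' @param classifySeparation separation (degrees) whose tuning curve is used
#'   for classification (default 120).
#' @return list with `directions`, `gratingTuning`, `plaidTuning` (matrix
#'   directions x separations), `classification`, `Rp`, `Rc`, `zp`, `zc`,
#'   `peakCount`
#' @export
plaidAnalysis <- function(model, stack = NULL, unit = NULL, sf, tf, size,
                          duration = 40L,
                          separations = c(30, 60, 90, 120, 150),
                          directions = seq(0, 345, by = 15),
                          maskRadius = NULL, classifySeparation = 120) {
  respond <- .unitResponder(model, stack, unit)
  gr <- vapply(directions, function(d)
    mean(respond(makeGrating(d, sf, tf, size, duration))), numeric(1))
  pl <- matrix(0, length(directions), length(separations),
               dimnames = list(NULL, paste0("sep", separations)))
  for (k in seq_along(separations)) {
    for (i in seq_along(directions))
      pl[i, k] <- mean(respond(makePlaid(directions[i], separations[k], sf,
                                         tf, size, duration,
                                         maskRadius = maskRadius)))
  }
  sep <- classifySeparation
  kSel <- which.min(abs(separations - sep))
  sep <- separations[kSel]
  shift <- function(v, deg) { # tuning curve rotated by deg on the grid
    step <- diff(directions[1:2])
    k <- round(deg / step)
    v[((seq_along(v) - 1 - k) %% length(v)) + 1]
  }
  componentPred <- (shift(gr, sep / 2) + shift(gr, -sep / 2)) / 2
  observed <- pl[, kSel]
  if (max(observed) == 0 || max(gr) == 0) {
    classification <- "unclassified"
    pc <- list(Rp = NA_real_, Rc = NA_real_); zp <- zc <- NA_real_
  } else {
    pc <- .plaidPartialCorrelations(observed, gr, componentPred)
    n <- length(directions)
    zp <- atanh(pmin(pmax(pc$Rp, -0.9999), 0.9999)) * sqrt(n - 3)
    zc <- atanh(pmin(pmax(pc$Rc, -0.9999), 0.9999)) * sqrt(n - 3)
    classification <- if (is.na(zp) || is.na(zc)) "unclassified"
      else if (zp - max(zc, 0) >= 1.28) "pattern"
      else if (zc - max(zp, 0) >= 1.28) "component"
      else "unclassified"
  }
  list(directions = directions, gratingTuning = gr, plaidTuning = pl,
       classification = classification, Rp = pc$Rp, Rc = pc$Rc, zp = zp,
       zc = zc,
       peakCount = .peakCount(observed, diff(directions[1:2])))
}
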