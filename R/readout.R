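# Scoring feature models against neural recordings: reduced latent features,
# a linear-nonlinear Poisson readout, and the noise-normalized correlation
# coefficient CCnorm.

#' Build latent features from model activity
#'
#' Concatenates the (flattened) model unit activity at times t-1 and t-2 and
#' projects it onto the leading principal components (centered), so features
#' at time t predict responses at time t with a transduction/conductance
#' latency span. The reduction basis must be fit on cross-validation data
#' only; pass it back via `basis` to transform held-out data.
#'
#' @param activity matrix (time bins x units), the flattened model activity.
#' @param nComponents target dimensionality (reference setting 500); capped at
#'   the available rank with a warning.
#' @param span time lags to concatenate (default t-1 and t-2; use 0 for
#'   static-stimulus features).
#' @param basis optional basis from a previous call (list with `mean`,
#'   `rotation`, `span`).
#' @return list with `features` (time x components), `basis`, and `valid`
#'   (logical index of time bins retained; lags reaching before the first bin
#'   are dropped)
#' @export
buildLatent <- function(activity, nComponents = 500L, span = c(1L, 2L),
                        basis = NULL) {
  activity <- as.matrix(activity)
  T <- nrow(activity)
  maxLag <- max(span)
  valid <- seq_len(T) > maxLag
  lagged <- do.call(cbind, lapply(span, function(l)
    activity[which(valid) - l, , drop = FALSE]))
  if (!is.null(basis)) {
    feats <- sweep(lagged, 2, basis$mean) %*% basis$rotation
    return(list(features = feats, basis = basis, valid = valid))
  }
  nc <- min(nComponents, ncol(lagged), nrow(lagged) - 1L)
  if (nc < nComponents)
    warning(sprintf("only %d components available (%d requested)", nc,
                    nComponents))
  pc <- prcomp(lagged, center = TRUE, scale. = FALSE, rank. = nc)
  basis <- list(mean = colMeans(lagged), rotation = pc$rotation, span = span,
                sdev = pc$sdev[seq_len(nc)])
  list(features = pc$x, basis = basis, valid = valid)
}

#' Fit the linear-nonlinear Poisson readout
#'
#' Per neuron l, predicted rate r^ = softplus(m_l' h + d_l); weights minimize
#' the negative Poisson likelihood -(1/LT) sum(r log r^ - r^) plus an L1
#' penalty lambda_read * sum|m|, with Adam (batch 1024, learning rate 0.002,
#' 300 epochs by default).
#'
#' @param latent matrix (time x latent dims).
#' @param responses matrix (time x neurons) of spike counts (trial-mean or
#'   single-trial).
#' @param lambdaRead L1 penalty.
#' @param seed RNG seed.
#' @param epochs,batchSize,lr optimizer settings.
#' @return a [ReadoutModel-class]
#' @export
fitReadout <- function(latent, responses, lambdaRead = 1e-4, seed = 1L,
                       epochs = 300L, batchSize = 1024L, lr = 0.002) {
  latent <- as.matrix(latent)
  responses <- as.matrix(responses)
  stopifnot(nrow(latent) == nrow(responses))
  T <- nrow(latent); L <- ncol(responses); D <- ncol(latent)
  set.seed(seed)
  m <- matrix(rnorm(D * L, sd = 0.01), D, L)
  d <- rep(0.1, L)
  st <- list(mm = matrix(0, D, L), vm = matrix(0, D, L), md = numeric(L),
             vd = numeric(L), t = 0L)
  log <- data.frame(epoch = seq_len(epochs), loss = NA_real_)
  nBatch <- ceiling(T / batchSize)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(T)
    epLoss <- 0
    for (bk in seq_len(nBatch)) {
      idx <- ord[((bk - 1L) * batchSize + 1L):min(bk * batchSize, T)]
      X <- latent[idx, , drop = FALSE]
      R <- responses[idx, , drop = FALSE]
      eta <- sweep(X %*% m, 2, d, "+")
      rhat <- softplus(eta)
      nb <- length(idx)
      loss <- -sum(R * log(pmax(rhat, 1e-12)) - rhat) / (L * nb) +
        lambdaRead * sum(abs(m))
      if (!is.finite(loss)) stop("readout fit diverged")
      epLoss <- epLoss + loss / nBatch
      dEta <- ((1 - R / pmax(rhat, 1e-12)) * stats::plogis(eta)) / (L * nb)
      gm <- crossprod(X, dEta) + lambdaRead * sign(m)
      gd <- colSums(dEta)
      st$t <- st$t + 1L
      bc1 <- 1 - 0.9^st$t; bc2 <- 1 - 0.999^st$t
      st$mm <- 0.9 * st$mm + 0.1 * gm
      st$vm <- 0.999 * st$vm + 0.001 * gm^2
      st$md <- 0.9 * st$md + 0.1 * gd
      st$vd <- 0.999 * st$vd + 0.001 * gd^2
      m <- m - lr * (st$mm / bc1) / (sqrt(st$vm / bc2) + 1e-8)
      d <- d - lr * (st$md / bc1) / (sqrt(st$vd / bc2) + 1e-8)
    }
    log$loss[ep] <- epLoss
  }
  new("ReadoutModel", weights = m, bias = d, lambdaRead = lambdaRead,
      log = log)
}

#' Predicted rates from a fitted readout
#'
#' @param object a [ReadoutModel-class].
#' @param latent matrix (time x latent dims).
#' @return matrix (time x neurons) of positive rates
#' @export
predictRates <- function(object, latent) {
  softplus(sweep(as.matrix(latent) %*% object@weights, 2, object@bias, "+"))
}

#' Maximum achievable correlation given neural noise
#'
#' Signal-power construction from trial-to-trial variability: with N trials,
#' signal power SP = (var(sum over trials) - sum of per-trial variances) /
#' (N (N - 1)) and CCmax = sqrt(SP / var(trial mean)). Neurons whose
#' signal-power estimate is not positive are flagged with NA.
#'
#' @param responses matrix (trials x time) for one neuron.
#' @return CCmax estimate
#' @export
ccMax <- function(responses) {
  responses <- as.matrix(responses)
  N <- nrow(responses)
  if (N < 2L) stop("at least 2 repeats are required")
  sp <- (var(colSums(responses)) - sum(apply(responses, 1, var))) /
    (N * (N - 1))
  vm <- var(colMeans(responses))
  if (!is.finite(sp) || sp <= 0 || vm == 0) return(NA_real_)
  min(sqrt(sp / vm), 1)
}

#' Noise-normalized correlation coefficient
#'
#' CCnorm = cor(prediction, trial-mean response) / CCmax: 0 means
#' uncorrelated, 1 as correlated as the neural noise permits.
#'
#' @param prediction predicted rate over time.
#' @param responses matrix (trials x time).
#' @return CCnorm (NA, flagged by a warning, when prediction or response has
#'   zero variance or the noise ceiling is undefined)
#' @export
ccNorm <- function(prediction, responses) {
  responses <- as.matrix(responses)
  mresp <- colMeans(responses)
  if (sd(prediction) == 0 || sd(mresp) == 0) {
    warning("zero-variance prediction or response: CCnorm undefined")
    return(NA_real_)
  }
  cmax <- ccMax(responses)
  if (is.na(cmax)) {
    warning("non-positive signal-power estimate: CCnorm undefined")
    return(NA_real_)
  }
  cor(prediction, mresp) / cmax
}

#' Cross-validate the readout penalty
#'
#' Five-fold cross-validation over the cross-validation split: for each
#' lambda on a log-spaced grid (reference 9 values, 10^-6.5 to 10^-2.5) the
#' readout is fitted on 80% of the bins and scored by mean CCnorm on the
#' remaining 20%; the final readout is refit on all cross-validation data at
#' the best lambda.
#'
#' @param latent matrix (time x latent dims), cross-validation rows only.
#' @param responses 3D array (trial x time x neuron) aligned with `latent`.
#' @param lambdaGrid candidate penalties.
#' @param folds number of folds (default 5); fold blocks are contiguous in
#'   time unless `foldId` is given (e.g. stimulus-file labels).
#' @param foldId optional integer fold assignment per time bin.
#' @param seed,epochs,batchSize,lr passed to [fitReadout()].
#' @return list with `lambda`, `readout` (refit on everything), `cvScores`
#'   (matrix lambda x fold of mean CCnorm), `dropped` (neurons with zero
#'   variance, excluded from selection)
#' @export
crossValidateLambda <- function(latent, responses,
                                lambdaGrid = 10^seq(-6.5, -2.5, by = 0.5),
                                folds = 5L, foldId = NULL, seed = 1L,
                                epochs = 300L, batchSize = 1024L, lr = 0.002) {
  latent <- as.matrix(latent)
  T <- nrow(latent)
  stopifnot(dim(responses)[2] == T)
  L <- dim(responses)[3]
  mresp <- apply(responses, c(2, 3), mean)
  dropped <- which(apply(mresp, 2, sd) == 0)
  if (length(dropped))
    warning(sprintf("%d zero-variance neuron(s) dropped from selection",
                    length(dropped)))
  if (is.null(foldId)) foldId <- ceiling(seq_len(T) / (T / folds))
  scores <- matrix(NA_real_, length(lambdaGrid), folds)
  for (li in seq_along(lambdaGrid)) {
    for (fd in seq_len(folds)) {
      te <- foldId == fd
      fit <- fitReadout(latent[!te, , drop = FALSE],
                        mresp[!te, , drop = FALSE], lambdaGrid[li],
                        seed = childSeed(seed, li * folds + fd),
                        epochs = epochs, batchSize = batchSize, lr = lr)
      pred <- predictRates(fit, latent[te, , drop = FALSE])
      cc <- vapply(setdiff(seq_len(L), dropped), function(l)
        suppressWarnings(ccNorm(pred[, l], responses[, te, l])), numeric(1))
      scores[li, fd] <- mean(cc, na.rm = TRUE)
    }
  }
  best <- which.max(rowMeans(scores))
  readout <- fitReadout(latent, mresp, lambdaGrid[best],
                        seed = childSeed(seed, 1L), epochs = epochs,
                        batchSize = batchSize, lr = lr)
  list(lambda = lambdaGrid[best], readout = readout, cvScores = scores,
       dropped = dropped)
}

#' Paired bootstrap comparison of two models' scores
#'
#' Resamples per-neuron prediction scores (paired, with replacement) and
#' reports p, the fraction of resamples in which model A's mean exceeds model
#' B's (1 - p favoring B).
#'
#' @param scoresA,scoresB per-neuron scores, equal length.
#' @param nBoot resamples (default 10000).
#' @param seed RNG seed.
#' @return list with `p` and `pOther` = 1 - p
#' @export
bootstrapCompare <- function(scoresA, scoresB, nBoot = 10000L, seed = 1L) {
  if (length(scoresA) != length(scoresB))
    stop("paired scores must have equal length")
  set.seed(seed)
  n <- length(scoresA)
  wins <- 0
  for (b in seq_len(nBoot)) {
    idx <- sample.int(n, n, replace = TRUE)
    mA <- mean(scoresA[idx]); mB <- mean(scoresB[idx])
    wins <- wins + (mA > mB) + 0.5 * (mA == mB) # ties split evenly
  }
  list(p = wins / nBoot, pOther = 1 - wins / nBoot)
}

#' Synthetic neurons with a planted sparse readout
#'
#' Ground-truth rates are softplus(planted sparse readout of the supplied
#' latent features); trials are independent Poisson draws. Planted parameters
#' are returned for recovery tests.
#'
#' @param features matrix (time x latent dims), the true latents.
#' @param nNeurons number of neurons.
#' @param sparsity fraction of zero weights per neuron.
#' @param nTrials repeats.
#' @param seed RNG seed.
#' @param gain,bias scale/offset applied before the softplus (defaults give
#'   a few counts per bin on standardized features).
#' @return list with `responses` (trial x time x neuron), `rates`, `weights`
#'   (planted), `bias`
#' @export
synthNeurons <- function(features, nNeurons, sparsity = 0.9, nTrials = 10L,
                         seed = 1L, gain = 1, bias = 0.5) {
  features <- as.matrix(features)
  set.seed(seed)
  D <- ncol(features); T <- nrow(features)
  sdv <- apply(features, 2, sd)
  Z <- sweep(sweep(features, 2, colMeans(features)), 2,
             ifelse(sdv > 0, sdv, 1), "/")
  m <- matrix(rnorm(D * nNeurons), D, nNeurons)
  mask <- matrix(runif(D * nNeurons) >= sparsity, D, nNeurons)
  m <- m * mask / sqrt(pmax(colSums(mask), 1))[col(m)]
  rates <- softplus(gain * (Z %*% m) + bias)
  responses <- array(rpois(nTrials * T * nNeurons,
                           rep(aperm(array(rates, c(T, nNeurons, nTrials)),
                                     c(3, 1, 2)))),
                     dim = c(nTrials, T, nNeurons))
  list(responses = responses, rates = rates, weights = m, bias = rep(bias,
                                                                     nNeurons))
}

#' Score a model at several input scales and report the best
#'
#' Runs the full latent/readout pipeline per spatial rescaling of the model
#' input and per stack, and reports the best (scale, stack) by mean CCnorm on
#' the held-out test split.
#'
#' @param model a [HierarchicalModel-class].
#' @param stimulus (y, x, t) array, the full stimulus movie at native
#'   resolution.
#' @param responses array (trial x time x neuron) aligned to the stimulus
#'   frames.
#' @param scales spatial rescalings of the model input (reference 0.66, 1,
#'   1.5).
#' @param testFraction held-out fraction (default 0.2, the final bins).
#' @param nComponents latent dimensionality.
#' @param lambdaGrid,folds,epochs,batchSize,lr,seed readout settings.
#' @return list with `best` (scale, stack, meanScore), `scores` (per-neuron
#'   CCnorm at the best setting), `table` (all scale/stack mean scores)
#' @export
rescaleSearch <- function(model, stimulus, responses,
                          scales = c(0.66, 1, 1.5), testFraction = 0.2,
                          nComponents = 500L,
                          lambdaGrid = 10^seq(-6.5, -2.5, by = 0.5),
                          folds = 5L, epochs = 300L, batchSize = 1024L,
                          lr = 0.002, seed = 1L) {
  T <- dim(stimulus)[3]
  tab <- NULL
  best <- NULL
  for (sc in scales) {
    side <- round(dim(stimulus)[1] * sc)
    stim <- if (sc == 1) stimulus else .bilinearResize(stimulus, side)
    acts <- forwardHierarchy(model, stim)
    for (z in seq_along(acts)) {
      A <- acts[[z]]
      d <- dim(A)
      act <- matrix(aperm(A, c(3, 1, 2, 4)), nrow = d[3])
      # align hidden time steps with the final stimulus frames they consume
      offset <- T - d[3]
      resp <- responses[, (offset + 1L):T, , drop = FALSE]
      lat <- buildLatent(act, nComponents)
      keep <- which(lat$valid)
      resp <- resp[, keep, , drop = FALSE]
      nT <- length(keep)
      nTest <- max(1L, round(testFraction * nT))
      teIdx <- (nT - nTest + 1L):nT
      cvIdx <- seq_len(nT - nTest)
      cv <- crossValidateLambda(lat$features[cvIdx, , drop = FALSE],
                                resp[, cvIdx, , drop = FALSE],
                                lambdaGrid, folds, seed = seed,
                                epochs = epochs, batchSize = batchSize,
                                lr = lr)
      pred <- predictRates(cv$readout, lat$features[teIdx, , drop = FALSE])
      cc <- vapply(seq_len(dim(resp)[3]), function(l)
        suppressWarnings(ccNorm(pred[, l], resp[, teIdx, l])), numeric(1))
      ms <- mean(cc, na.rm = TRUE)
      tab <- rbind(tab, data.frame(scale = sc, stack = z, meanScore = ms))
      if (is.null(best) || (is.finite(ms) && ms > best$meanScore))
        best <- list(scale = sc, stack = z, meanScore = ms, scores = cc,
                     lambda = cv$lambda)
    }
  }
  list(best = best[c("scale", "stack", "meanScore", "lambda")],
       scores = best$scores, table = tab)
}
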