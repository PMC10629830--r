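test_that("latent features are centered PCs with sane rank behavior", {
  set.seed(1)
  act <- matrix(rnorm(400 * 30), 400, 30)
  expect_warning(lat <- buildLatent(act, nComponents = 500L),
                 "components available")
  expect_equal(ncol(lat$features), 60L) # 2 lags x 30 units
  v <- apply(lat$features, 2, var)
  expect_true(all(diff(v) <= 1e-10)) # non-increasing component variances
  # lags reaching before the first bin are dropped
  expect_equal(sum(lat$valid), 398L)
  # nested-basis reconstruction: more components reconstruct no worse
  lagged <- cbind(act[2:399, ], act[1:398, ])
  recErr <- function(k) {
    ctr <- sweep(lagged, 2, lat$basis$mean)
    proj <- ctr %*% lat$basis$rotation[, 1:k]
    back <- proj %*% t(lat$basis$rotation[, 1:k])
    mean((ctr - back)^2)
  }
  expect_lte(recErr(40), recErr(10))
  # a frozen basis transforms new data reproducibly
  lat2 <- buildLatent(act, basis = lat$basis)
  expect_equal(lat2$features, lat$features)
})

test_that("readout fitting recovers a planted sparse Poisson readout", {
  set.seed(2)
  T <- 3000; D <- 40
  X <- matrix(rnorm(T * D), T, D)
  mTrue <- numeric(D); mTrue[sample(D, 8)] <- rnorm(8, sd = 1)
  rate <- TemporalPrediction:::softplus(X %*% mTrue + 0.5)
  r <- matrix(rpois(T, rate), ncol = 1)
  fit <- fitReadout(X, r, lambdaRead = 1e-4, seed = 3, epochs = 150)
  expect_gt(cor(readoutWeights(fit)[, 1], mTrue), 0.9)
  expect_true(all(predictRates(fit, X) > 0))
  # training objective decreases (smoothed)
  ll <- fit@log$loss
  sm <- stats::filter(ll, rep(1 / 10, 10), sides = 1)
  expect_lt(sm[length(ll)], sm[15])
  # a huge penalty drives the weights to (near) zero
  big <- fitReadout(X, r, lambdaRead = 10, seed = 3, epochs = 60)
  expect_lt(sum(abs(readoutWeights(big))),
            0.01 * sum(abs(readoutWeights(fit))))
})

test_that("noise ceiling and CCnorm behave at the limits", {
  set.seed(4)
  signal <- sin(seq(0, 20, length.out = 300)) + 1.5
  noiseless <- matrix(rep(signal, 4), 4, byrow = TRUE)
  expect_equal(ccMax(noiseless), 1)
  expect_equal(ccNorm(signal, noiseless), 1)
  # Poisson neuron with known rate: trial mean predicted by the true rate
  resp <- matrix(rpois(200 * 300, rep(signal * 4, each = 200)), 200)
  expect_gt(ccNorm(signal, resp), 0.97)
  expect_lt(ccNorm(signal, resp), 1.05)
  # an independent prediction scores near zero
  indep <- rnorm(300)
  expect_lt(abs(ccNorm(indep, resp)), 2 / sqrt(300) * 3)
  expect_warning(ccNorm(rep(1, 300), resp), "zero-variance")
  expect_error(ccMax(matrix(1, 1, 10)), "2 repeats")
})

test_that("ceiling error shrinks as trials grow", {
  set.seed(5)
  signal <- exp(sin(seq(0, 30, length.out = 400)))
  dev <- sapply(c(4, 16, 64), function(n) {
    reps <- replicate(20, {
      resp <- matrix(rpois(n * 400, rep(signal * 3, each = n)), n)
      suppressWarnings(ccNorm(signal, resp))
    })
    mean(abs(reps - 1))
  })
  expect_true(dev[3] < dev[1])
})

test_that("lambda cross-validation selects sensibly", {
  grid <- 10^seq(-6.5, -2.5, by = 0.5)
  expect_equal(length(grid), 9L)
  expect_equal(diff(log10(grid))[1], 0.5)
  set.seed(6)
  T <- 500; D <- 12
  X <- matrix(rnorm(T * D), T, D)
  mTrue <- numeric(D); mTrue[1:3] <- c(1, -0.8, 0.6)
  rate <- TemporalPrediction:::softplus(X %*% mTrue + 1)
  resp <- array(rpois(6 * T, rep(rate, each = 6)), c(6, T, 1))
  # degenerate single-lambda grid is returned unchanged
  one <- crossValidateLambda(X, resp, lambdaGrid = 1e-4, folds = 3L,
                             epochs = 40, seed = 7)
  expect_equal(one$lambda, 1e-4)
  # zero-variance neurons are dropped with a flag
  resp2 <- array(0, c(6, T, 2)); resp2[, , 1] <- resp[, , 1]
  expect_warning(cv2 <- crossValidateLambda(X, resp2, lambdaGrid = 1e-4,
                                            folds = 3L, epochs = 30,
                                            seed = 7), "dropped")
  expect_equal(cv2$dropped, 2L)
  # the selected lambda is within one grid step of the oracle best
  smallGrid <- 10^c(-5, -3, -1)
  cv <- crossValidateLambda(X, resp, lambdaGrid = smallGrid, folds = 3L,
                            epochs = 60, seed = 8)
  oracle <- sapply(smallGrid, function(l) {
    fit <- fitReadout(X[1:400, ], apply(resp[, 1:400, , drop = FALSE],
                                        c(2, 3), mean), l, seed = 9,
                      epochs = 60)
    suppressWarnings(ccNorm(predictRates(fit, X[401:500, ])[, 1],
                            resp[, 401:500, 1]))
  })
  expect_lte(abs(which(smallGrid == cv$lambda) - which.max(oracle)), 1)
})

test_that("paired bootstrap is symmetric under ties and sharp under shifts", {
  set.seed(10)
  a <- rnorm(23)
  expect_equal(bootstrapCompare(a, a, nBoot = 2000, seed = 1)$p, 0.5)
  expect_equal(bootstrapCompare(a + 1, a, nBoot = 2000, seed = 1)$p, 1)
  expect_error(bootstrapCompare(a, a[-1]), "equal length")
  # planted 0.5 SD shift: bootstrap p matches a paired-t oracle within MC error
  d <- rnorm(23, mean = 0.5, sd = 1)
  b <- rnorm(23)
  p <- bootstrapCompare(b + d, b, nBoot = 4000, seed = 2)$p
  # the bootstrap p approximates P(mean(d*) > 0); oracle via the normal
  # approximation to the resampled mean
  oracle <- pnorm(mean(d) / (sd(d) / sqrt(23)))
  expect_lt(abs(p - oracle), 0.08)
})

test_that("synthetic neurons have the planted structure", {
  set.seed(11)
  feats <- matrix(rnorm(300 * 20), 300, 20)
  sn <- synthNeurons(feats, nNeurons = 5, sparsity = 0.8, nTrials = 1000,
                     seed = 12)
  # infinite-trial limit: trial mean approaches the planted rate
  tm <- apply(sn$responses, c(2, 3), mean)
  for (l in 1:5) expect_gt(cor(tm[, l], sn$rates[, l]), 0.99)
  # sparsity ordering of planted supports
  dense <- synthNeurons(feats, 5, sparsity = 0, nTrials = 2, seed = 12)
  expect_gt(sum(dense$weights != 0), sum(sn$weights != 0))
  sn2 <- synthNeurons(feats, 5, sparsity = 0.8, nTrials = 1000, seed = 12)
  expect_identical(sn$responses, sn2$responses)
})

test_that("repeated-frame featurization settles to a steady state", {
  # images are handled as repeated identical frames: after the valid-conv
  # transient every hidden time step is identical
  m <- filterBankModel(list(gaborPatch(9, 45, 0.15, 2),
                            dogPatch(9)), inputSide = 24L, clipLen = 8L,
                       depth = 3L)
  img <- matrix(rnorm(24 * 24), 24)
  stim <- array(img, c(24, 24, 8))
  H <- forwardHierarchy(m, stim)[[1]]
  for (t in 2:dim(H)[3]) expect_equal(H[, , t, ], H[, , 1, ])
})

test_that("rescale search picks the planted scale and the best stack", {
  set.seed(13)
  m <- filterBankModel(list(gaborPatch(11, 30, 0.12, 2.5),
                            gaborPatch(11, 120, 0.12, 2.5),
                            dogPatch(11)), inputSide = 32L, clipLen = 400L)
  stim <- array(rnorm(32 * 32 * 400), c(32, 32, 400))
  acts <- forwardHierarchy(m, stim)[[1]]
  d <- dim(acts)
  act <- matrix(aperm(acts, c(3, 1, 2, 4)), nrow = d[3])
  lat <- buildLatent(act, nComponents = 30L)
  sn <- synthNeurons(lat$features, nNeurons = 6, sparsity = 0.5,
                     nTrials = 8, seed = 14, gain = 1.5, bias = 1)
  resp <- array(0, c(8, 400, 6))
  resp[, which(lat$valid), ] <- sn$responses
  out <- rescaleSearch(m, stim, resp, scales = c(0.66, 1, 1.5),
                       nComponents = 30L, lambdaGrid = c(1e-5, 1e-4),
                       folds = 3L, epochs = 50)
  expect_equal(out$best$scale, 1)
  expect_equal(out$best$meanScore, max(out$table$meanScore, na.rm = TRUE))
})
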