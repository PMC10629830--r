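test_that("circular variance has its closed-form values", {
  dirs <- seq(0, 355, by = 5)
  expect_equal(circularVariance(rep(2, 72), dirs), 1)
  delta <- rep(0, 72); delta[10] <- 5
  expect_equal(circularVariance(delta, dirs), 0)
  # equal responses at theta and theta + 90 only: doubling cancels exactly
  two <- rep(0, 72); two[1] <- 3; two[1 + 90 / 5] <- 3
  expect_equal(circularVariance(two, dirs), 1)
  expect_warning(cv <- circularVariance(rep(0, 72), dirs), "undefined")
  expect_true(is.na(cv))
  expect_true(circularVariance(runif(72), dirs) >= 0)
})

test_that("orientation bandwidth follows the smoothed 70.7% crossing", {
  dirs <- seq(0, 355, by = 5)
  expect_equal(orientationBandwidth(rep(1, 72), dirs), 180)
  # delta tuning: bandwidth is set by the Hanning kernel alone; oracle is the
  # numerically computed 70.7% crossing of the kernel itself
  delta <- rep(0, 72); delta[19] <- 1
  sm <- TemporalPrediction:::.hanningSmooth(delta, 5)
  pk <- which.max(sm)
  dense <- approx(seq(-180, 175, 5), sm[((seq_along(sm) - 1 + pk - 37) %% 72) + 1],
                  xout = seq(-180, 175, 0.01))
  lvl <- max(sm) / sqrt(2)
  oracle <- mean(abs(range(dense$x[dense$y > lvl])))
  expect_lt(abs(orientationBandwidth(delta, dirs) - oracle), 0.6)
  # raised-cosine tuning of known width vs dense-grid numeric solution
  width <- 60
  rc <- ifelse(pmin(abs(dirs - 90), 360 - abs(dirs - 90)) < width,
               cos(pi * pmin(abs(dirs - 90), 360 - abs(dirs - 90)) /
                     (2 * width))^2, 0)
  smRc <- TemporalPrediction:::.hanningSmooth(rc, 5)
  pk <- which.max(smRc)
  densRc <- approx(dirs, smRc, xout = seq(0, 355, 0.01))
  lvl <- smRc[pk] / sqrt(2)
  above <- densRc$x[densRc$y > lvl]
  oracle <- (max(above) - min(above)) / 2
  expect_lt(abs(orientationBandwidth(rc, dirs) - oracle), 1)
})

test_that("modulation ratio matches closed forms", {
  t <- 0:199
  cpf <- 0.05 # cycles per frame, 10 full cycles in the window
  expect_equal(modulationRatio(rep(3, 200), cpf)$MR, 0)
  mr1 <- modulationRatio(1 + sin(2 * pi * cpf * t), cpf)
  expect_equal(mr1$F0, 1, tolerance = 1e-9)
  expect_equal(mr1$F1, 1, tolerance = 1e-9)
  expect_equal(mr1$MR, 1, tolerance = 1e-9)
  # half-wave-rectified sinusoid: F0 = 1/pi, F1 = 1/2, MR = pi/2
  half <- pmax(0, sin(2 * pi * cpf * t))
  mrH <- modulationRatio(half, cpf)
  expect_equal(mrH$F0, 1 / pi, tolerance = 1e-2)
  expect_equal(mrH$F1, 1 / 2, tolerance = 1e-2)
  expect_equal(mrH$MR, pi / 2, tolerance = 0.02)
  expect_warning(u <- modulationRatio(rep(0, 100), cpf), "undefined")
  expect_true(is.na(u$MR))
})

test_that("direction selectivity indices match their definitions", {
  dirs <- seq(0, 355, by = 5)
  mk <- function(rp, rnp) { r <- rep(0, 72); r[1] <- rp; r[37] <- rnp; r }
  sym <- directionSelectivity(mk(10, 10), dirs, 0)
  expect_equal(sym$dsi1, 0)
  full <- directionSelectivity(mk(10, 0), dirs, 0)
  expect_equal(c(full$dsi1, full$dsi2, full$dsi3), c(1, 1, 1))
  # baseline-corrected index exceeds 1 when rnp < rnull
  d3 <- directionSelectivity(mk(10, 1), dirs, rnull = 2)
  expect_equal(d3$dsi3, 1.125)
  und <- directionSelectivity(rep(0, 72), dirs, 0)
  expect_true(is.na(und$dsi1) && is.na(und$dsi2))
})

test_that("classification follows the simple/complex/non-oriented criteria", {
  expect_equal(classifyUnit(0.3, 1.6, fitCorr = 0.8, dsi1 = 0.2)$label,
               "simple")
  expect_equal(classifyUnit(0.5, 0.4)$label, "complex")
  expect_equal(classifyUnit(0.95, 1.2, fitCorr = 0.9)$label, "non_oriented")
  expect_equal(classifyUnit(0.3, 1.2, fitCorr = 0.2)$label, "non_oriented")
  expect_equal(classifyUnit(NA, 1.2, fitCorr = 0.9)$label, "excluded")
  expect_true(classifyUnit(0.3, 1.6, 0.8, dsi1 = 0.7)$directionTuned)
  expect_false(classifyUnit(0.3, 1.6, 0.8, dsi1 = 0.3)$directionTuned)
})

test_that("weak responders are excluded by the population threshold", {
  expect_equal(unitExclusion(c(100, 10, 0.5), 0.01), c(TRUE, TRUE, FALSE))
  expect_true(all(unitExclusion(rep(4, 7), 0.01)))
  expect_equal(unitExclusion(c(1000, 2, 0.5), 0.001), c(TRUE, TRUE, FALSE))
})

test_that("optimal-grating search recovers a planted filter and is an argmax", {
  m <- filterBankModel(list(gaborPatch(15, 60, 0.12, 3)), inputSide = 40L,
                       clipLen = 12L)
  gr <- gratingResponses(m, size = 40L, directions = seq(0, 355, 15),
                         sfs = c(0.03, 0.06, 0.12, 0.24), tfs = c(1.25, 5),
                         duration = 20L)
  opt <- findOptimalGrating(gr, 1, 1)
  expect_equal(unname(opt$params["sf"]), 0.12)
  # direction within one grid step of the planted orientation (mod 180)
  dd <- min(abs(c(opt$params["direction"] - 60,
                  opt$params["direction"] - 240)))
  expect_lte(dd, 15)
  # argmax contract: optimum response >= every grid response
  allResp <- rowMeans(gr$traces[[1]][, 1, ])
  expect_gte(opt$response, max(allResp) - 1e-12)
  # zero unit is flagged unresponsive
  m0 <- filterBankModel(list(matrix(0, 15, 15)), inputSide = 40L,
                        clipLen = 12L)
  gr0 <- gratingResponses(m0, size = 40L, directions = c(0, 90),
                          sfs = 0.1, tfs = 1.25, duration = 20L)
  expect_true(findOptimalGrating(gr0, 1, 1)$unresponsive)
})

test_that("hand-built population is classified with >= 90% accuracy", {
  # stack 1: quadrature quadruples (energy-style complex afferents), plain
  # Gabors (simple), and a center-surround blob (non-oriented)
  filters <- list()
  truth <- c()
  quadThetas <- c(20, 110)
  for (th in quadThetas)
    for (ph in c(0, pi / 2, pi, 3 * pi / 2))
      filters[[length(filters) + 1]] <- gaborPatch(15, th, 0.12, 3, phase = ph)
  simpleThetas <- c(45, 135, 90)
  for (th in simpleThetas)
    filters[[length(filters) + 1]] <- gaborPatch(15, th, 0.12, 3)
  filters[[length(filters) + 1]] <- dogPatch(15)
  m1 <- filterBankModel(filters, inputSide = 41L, clipLen = 12L)
  # stack 2 (1x1 kernels): sums each quadrature quadruple -> complex; passes
  # each simple and the blob through
  J1 <- length(filters)
  nOut <- length(quadThetas) + length(simpleThetas) + 1L
  truth <- c(rep("complex", length(quadThetas)),
             rep("simple", length(simpleThetas)), "non_oriented")
  s2 <- stackSpec(2L, hiddenLayerShape(stackSpecs(m1)[[1]])$shape, nOut,
                  c(1L, 1L, 1L))
  W2 <- array(0, c(1, 1, 1, J1, nOut))
  for (q in seq_along(quadThetas)) W2[1, 1, 1, (q - 1) * 4 + 1:4, q] <- 1
  for (s in seq_along(simpleThetas))
    W2[1, 1, 1, 8 + s, length(quadThetas) + s] <- 1
  W2[1, 1, 1, J1, nOut] <- 1
  w2 <- new("StackWeights", W = W2, b = numeric(nOut),
            M = array(0, c(1, 1, 1, nOut, J1)), c = numeric(J1))
  m <- new("HierarchicalModel", specs = list(stackSpecs(m1)[[1]], s2),
           weights = list(stackWeights(m1, 1), w2), trainingLog = list(),
           objective = "prediction")
  res <- characterizeModel(m, size = 41L, directions = seq(0, 355, 10),
                           sfs = c(0.06, 0.12, 0.24), tfs = c(1.25, 5),
                           duration = 24L, rcSamples = 6000, seed = 2)
  got <- res$label[res$stack == 2]
  expect_gte(mean(got == truth), 0.9)
})
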