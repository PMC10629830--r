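test_that("shape algebra matches the architecture arithmetic", {
  specs <- referenceSpecs()
  shapes <- lapply(specs, function(s) hiddenLayerShape(s)$shape)
  expect_equal(shapes[[1]], c(17L, 17L, 16L, 50L))
  expect_equal(shapes[[4]], c(11L, 11L, 4L, 400L))
  counts <- sapply(specs, function(s) hiddenLayerShape(s)$unitCount)
  expect_equal(counts, c(14450L, 22500L, 33800L, 48400L))
  # full-field kernel collapses to a single position
  sp <- stackSpec(1L, c(7L, 7L, 4L, 2L), 3L, c(7L, 7L, 4L))
  expect_equal(hiddenLayerShape(sp)$shape, c(1L, 1L, 1L, 3L))
  expect_error(hiddenLayerShape(
    stackSpec(1L, c(7L, 7L, 4L, 1L), 2L, c(7L, 7L, 4L), c(1L, 1L, 8L))),
    NA) # valid: floor((4-4)/8)+1 = 1
})

test_that("receptive extents accumulate kernel and stride", {
  specs <- referenceSpecs()
  exts <- lapply(1:4, function(z) unname(receptiveExtent(specs[1:z])))
  expect_equal(exts[[1]], c(21L, 21L, 5L))
  expect_equal(exts[[2]], c(41L, 41L, 9L))
  expect_equal(exts[[3]], c(61L, 61L, 13L))
  expect_equal(exts[[4]], c(81L, 81L, 17L))
  expect_equal(unname(receptiveExtent(specs[[1]])), specs[[1]]@kernel)
})

test_that("convForward equals the nested-loop oracle and respects relu", {
  set.seed(11)
  for (rep in 1:5) {
    d <- c(sample(4:6, 2), sample(3:5, 1), sample(1:3, 1))
    k <- c(sample(1:3, 2, replace = TRUE), sample(1:2, 1))
    s <- sample(1:2, 3, replace = TRUE)
    J <- sample(1:4, 1)
    sp <- stackSpec(1L, d, J, k, s)
    x <- array(rnorm(prod(d)), d)
    W <- array(rnorm(prod(k) * d[4] * J), c(k, d[4], J))
    b <- rnorm(J)
    wts <- new("StackWeights", W = W, b = b,
               M = array(0, c(k[1], k[2], 1L, J, d[4])), c = numeric(d[4]))
    H <- convForward(x, sp, wts)
    Href <- pmax(sweep(bruteConv3d(x, W, s), 4, b, "+"), 0)
    expect_lt(max(abs(H - Href)), 1e-6)
    expect_true(all(H >= 0))
    expect_equal(dim(H), hiddenLayerShape(sp)$shape, ignore_attr = TRUE)
  }
})

test_that("degenerate kernels behave as closed forms", {
  sp <- stackSpec(1L, c(6L, 6L, 4L, 1L), 2L, c(2L, 2L, 2L))
  w <- initStackWeights(sp, seed = 1)
  w@W[] <- 0
  w@b <- c(-1, 2)
  U <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  H <- convForward(U, sp, w)
  expect_true(all(H[, , , 1] == 0))
  expect_true(all(H[, , , 2] == 2))
  # 1x1x1 identity kernel returns relu(U)
  spI <- stackSpec(1L, c(6L, 6L, 4L, 1L), 1L, c(1L, 1L, 1L))
  wI <- initStackWeights(spI, seed = 1)
  wI@W[] <- 1; wI@b[] <- 0
  expect_equal(convForward(U, spI, wI)[, , , 1], pmax(U, 0),
               ignore_attr = TRUE)
  # shape mismatches name the offending axis
  expect_error(convForward(array(0, c(5, 6, 4, 1)), sp, w), "Y axis")
})

test_that("fractionally-strided head matches the dilate-and-convolve oracle", {
  set.seed(12)
  for (s in list(c(1L, 1L, 1L), c(2L, 2L, 1L), c(3L, 3L, 1L))) {
    k <- c(3L, 3L, 2L)
    hd <- c(4L, 5L, 3L)
    inShape <- c((hd[1:2] - 1L) * s[1:2] + k[1:2], hd[3] + k[3] - 1L, 2L)
    sp <- stackSpec(1L, inShape, 3L, k, s)
    w <- initStackWeights(sp, seed = s[1])
    H <- array(rnorm(prod(hd) * 3), c(hd, 3L))
    V <- predictFuture(H, sp, w)
    Vref <- sweep(brutePredict(H, w@M, s, k), 4, w@c, "+")
    expect_lt(max(abs(V - Vref)), 1e-6)
    # prediction recovers the input's spatial size
    expect_equal(dim(V)[1:2], unname(inShape[1:2]))
  }
})

test_that("stack-1 prediction matches the 181-pixel frame", {
  sp <- referenceSpecs()[[1]]
  w <- initStackWeights(sp, seed = 2)
  U <- array(rnorm(181 * 181 * 20), c(181, 181, 20))
  H <- convForward(U, sp, w)
  expect_equal(dim(H), c(17L, 17L, 16L, 50L), ignore_attr = TRUE)
  V <- predictFuture(H, sp, w)
  expect_equal(dim(V)[1:3], c(181L, 181L, 16L))
})

test_that("zero output kernels predict the bias everywhere", {
  sp <- stackSpec(1L, c(8L, 8L, 5L, 1L), 2L, c(3L, 3L, 2L))
  w <- initStackWeights(sp, seed = 3)
  w@M[] <- 0; w@c <- 0.7
  H <- convForward(array(rnorm(8 * 8 * 5), c(8, 8, 5)), sp, w)
  V <- predictFuture(H, sp, w)
  expect_true(all(V == 0.7))
})

test_that("prediction loss decomposes as mse plus lambda-linear penalty", {
  V <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  expect_equal(predictionLoss(V, V)$total, 0)
  expect_equal(predictionLoss(V + 1, V)$mseTerm, 1)
  # hand case: weights {0.5, -0.25}, lambda 0.1 -> l1 = 0.1 * 0.75 = 0.075
  w <- new("StackWeights",
           W = array(c(0.5, -0.25), c(2, 1, 1, 1, 1)), b = 0,
           M = array(0, c(2, 1, 1, 1, 1)), c = 0)
  V2 <- array(c(1, 2, 3, 4, 5, 6, 7, 8), c(2, 2, 2, 1))
  T2 <- V2 + 0.5
  pl <- predictionLoss(V2, T2, w, lambda = 0.1)
  expect_equal(pl$l1Term, 0.075)
  expect_equal(pl$mseTerm, 0.25)
  expect_equal(pl$total, 0.325)
  # total - mse scales linearly in lambda at fixed weights
  l1 <- sapply(c(0.1, 0.2, 0.4), function(l)
    predictionLoss(V2, T2, w, l)$total - predictionLoss(V2, T2, w, l)$mseTerm)
  expect_equal(l1[2] / l1[1], 2)
  expect_equal(l1[3] / l1[1], 4)
  expect_error(predictionLoss(V2 * NaN, T2), "NaN")
  expect_error(predictionLoss(V2, array(0, c(2, 2, 2, 2))), "congruent")
})

test_that("training reduces prediction error deterministically", {
  cs <- tinyClips(n = 14, side = 24L, seed = 6)
  sp <- stackSpec(1L, c(24L, 24L, 20L, 1L), 4L, c(8L, 8L, 4L), c(4L, 4L, 1L),
                  learningRate = 1e-2, l1Strength = 1e-6)
  fit1 <- trainStack(cs, sp, seed = 3, iterations = 40, batchSize = 8)
  fit2 <- trainStack(cs, sp, seed = 3, iterations = 40, batchSize = 8)
  expect_identical(fit1$log, fit2$log) # same seed, same data: identical runs
  expect_lt(fit1$log$valError[40], fit1$log$valError[1])
  # further training keeps improving the trained objective
  fitL <- trainStack(cs, sp, seed = 3, iterations = 150, batchSize = 8)
  expect_lt(fitL$valFinal, fit1$log$valError[40])
})

test_that("hierarchy chains shapes and feeds hidden activity upward", {
  cs <- tinyClips(n = 10, side = 24L, seed = 7)
  s1 <- stackSpec(1L, c(24L, 24L, 20L, 1L), 3L, c(8L, 8L, 4L), c(4L, 4L, 1L),
                  learningRate = 1e-2, l1Strength = 1e-6)
  s2 <- stackSpec(2L, hiddenLayerShape(s1)$shape, 4L, c(2L, 2L, 3L),
                  learningRate = 1e-3, l1Strength = 1e-6)
  m <- trainHierarchy(cs, list(s1, s2), seed = 4, iterations = 25,
                      batchSize = 8, lambdaGrid = 1e-6)
  expect_s4_class(m, "HierarchicalModel")
  expect_equal(stackCount(m), 2L)
  expect_equal(stackSpecs(m)[[2]]@inputShape, hiddenLayerShape(s1)$shape)
  acts <- forwardHierarchy(m, clips(cs)[[1]])
  expect_equal(dim(acts[[1]]), hiddenLayerShape(s1)$shape, ignore_attr = TRUE)
  expect_equal(dim(acts[[2]]), hiddenLayerShape(s2)$shape, ignore_attr = TRUE)
  expect_true(all(acts[[2]] >= 0))
  # checkpoints round-trip
  path <- tempfile(fileext = ".rds")
  saveModel(m, path)
  m2 <- readModel(path)
  expect_equal(m2@weights[[1]]@W, m@weights[[1]]@W)
})

test_that("a trained first stack helps the second stack", {
  cs <- tinyClips(n = 12, side = 24L, seed = 8)
  s1 <- stackSpec(1L, c(24L, 24L, 20L, 1L), 3L, c(8L, 8L, 4L), c(4L, 4L, 1L),
                  learningRate = 1e-2, l1Strength = 1e-6)
  s2 <- stackSpec(2L, hiddenLayerShape(s1)$shape, 4L, c(2L, 2L, 3L),
                  learningRate = 1e-3, l1Strength = 1e-6)
  trained <- trainStack(cs, s1, seed = 5, iterations = 120, batchSize = 8)
  random <- initStackWeights(s1, seed = 99)
  split <- clipSplit(cs)
  up <- function(w) lapply(clips(cs), function(cl) convForward(cl, s1, w))
  fitT <- trainStack(up(trained$weights), s2, seed = 5, iterations = 60,
                     batchSize = 8, split = split)
  fitR <- trainStack(up(random), s2, seed = 5, iterations = 60,
                     batchSize = 8, split = split)
  # normalize by the variance of each stack-2 target stream (activity scales
  # differ between trained and random first stacks)
  scaleOf <- function(w) mean(sapply(up(w)[split == "validation"],
                                     function(a) mean(a^2)))
  expect_lt(fitT$valFinal / scaleOf(trained$weights),
            fitR$valFinal / scaleOf(random))
})

test_that("stronger L1 does not increase the fraction of large weights", {
  cs <- tinyClips(n = 10, side = 24L, seed = 9)
  sp <- stackSpec(1L, c(24L, 24L, 20L, 1L), 3L, c(8L, 8L, 4L), c(4L, 4L, 1L),
                  learningRate = 1e-2)
  fracBig <- sapply(c(1e-6, 1e-4, 1e-2), function(l) {
    fit <- trainStack(cs, sp, seed = 11, iterations = 120, batchSize = 8,
                      lambda = l)
    mean(abs(fit$weights@W) > 0.01)
  })
  expect_true(all(diff(fracBig) <= 1e-9))
})
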