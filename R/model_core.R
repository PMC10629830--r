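#' Construct a StackSpec
#'
#' @param index stack index (1-based).
#' @param inputShape integer (Y, X, T, I).
#' @param convUnits number of convolutional hidden units J.
#' @param kernel integer triple (y, x, t); a scalar pair is recycled.
#' @param stride integer triple (y, x, t).
#' @param learningRate Adam learning rate alpha.
#' @param l1Strength L1 weight penalty lambda.
#' @return a [StackSpec-class]
#' @export
stackSpec <- function(index, inputShape, convUnits, kernel,
                      stride = c(1L, 1L, 1L), learningRate = 1e-4,
                      l1Strength = 1e-6) {
  new("StackSpec", index = as.integer(index),
      inChannels = as.integer(inputShape[4]), convUnits = as.integer(convUnits),
      kernel = as.integer(kernel), stride = as.integer(stride),
      learningRate = learningRate, l1Strength = l1Strength,
      inputShape = as.integer(inputShape))
}

#' The standard four-stack architecture
#'
#' Returns the reference architecture: 181x181x20x1 video input; stacks of
#' 50, 100, 200 and 400 convolutional units; kernels 21x21x5 then 3x3x5;
#' spatial stride 10 in stack 1 and 1 above; learning rates 1e-2 then 1e-4;
#' L1 strengths 10^-4.5 then 1e-6.
#'
#' @param side input frame side, px (default 181).
#' @param clipLen input clip duration, frames (default 20).
#' @return list of four [StackSpec-class] objects
#' @export
referenceSpecs <- function(side = 181L, clipLen = 20L) {
  s1 <- stackSpec(1L, c(side, side, clipLen, 1L), 50L, c(21L, 21L, 5L),
                  c(10L, 10L, 1L), learningRate = 1e-2, l1Strength = 10^-4.5)
  specs <- list(s1)
  units <- c(100L, 200L, 400L)
  for (z in 2:4) {
    below <- hiddenLayerShape(specs[[z - 1L]])$shape
    specs[[z]] <- stackSpec(z, below, units[z - 1L], c(3L, 3L, 5L),
                            c(1L, 1L, 1L), learningRate = 1e-4,
                            l1Strength = 1e-6)
  }
  specs
}

#' A two-stack miniature architecture for desk-scale experiments
#'
#' A scaled-down hierarchy (8 and 16 convolutional units on 64x64 input) with
#' the same structural choices as the full model: a spatially strided first
#' stack with a large kernel, stride-1 upper stacks with 3x3x5 kernels.
#'
#' @param side input frame side (default 64).
#' @param clipLen clip duration in frames (default 20).
#' @param units hidden units per stack (default c(8, 16)).
#' @param l1 per-stack L1 strengths (low values favor Gabor-like over
#'   center-surround first-stack RFs).
#' @return list of [StackSpec-class]
#' @export
miniatureSpecs <- function(side = 64L, clipLen = 20L, units = c(8L, 16L),
                           l1 = c(1e-6, 1e-6)) {
  s1 <- stackSpec(1L, c(side, side, clipLen, 1L), units[1], c(16L, 16L, 5L),
                  c(6L, 6L, 1L), learningRate = 1e-2, l1Strength = l1[1])
  specs <- list(s1)
  for (z in seq_along(units)[-1]) {
    below <- hiddenLayerShape(specs[[z - 1L]])$shape
    specs[[z]] <- stackSpec(z, below, units[z], c(3L, 3L, 5L), c(1L, 1L, 1L),
                            learningRate = 1e-3, l1Strength = l1[z])
  }
  specs
}

#' Hidden-layer output shape and unit count of a stack
#'
#' Valid convolution with stride: every output dimension is
#' floor((input - kernel) / stride) + 1. The unit count multiplies the two
#' spatial dimensions by the number of convolutional units J (time excluded),
#' i.e. the number of hidden units over all spatial positions.
#'
#' @param spec a [StackSpec-class].
#' @return list with `shape` (Y_h, X_h, T_h, J) and `unitCount`
#' @export
hiddenLayerShape <- function(spec) {
  outDim <- as.integer((spec@inputShape[1:3] - spec@kernel) %/% spec@stride) + 1L
  if (any(outDim < 1L))
    stop("non-positive hidden dimension: kernel/stride incompatible with input")
  shape <- c(outDim, spec@convUnits)
  list(shape = shape, unitCount = shape[1] * shape[2] * shape[4])
}

#' Spatiotemporal extent of units in each stack
#'
#' The span of input pixels and frames a single hidden unit can receive from:
#' the kernel size for stack 1, and for deeper stacks
#' E_z = E_(z-1) + (kernel_z - 1) * prod(strides below), per axis.
#'
#' @param specs list of StackSpec, ordered from stack 1; the extent of the
#'   last element is returned.
#' @return integer (y, x, t) extent
#' @export
receptiveExtent <- function(specs) {
  if (is(specs, "StackSpec")) specs <- list(specs)
  ext <- specs[[1]]@kernel
  cumStride <- c(1L, 1L, 1L)
  for (z in seq_along(specs)[-1]) {
    cumStride <- cumStride * specs[[z - 1L]]@stride
    ext <- ext + (specs[[z]]@kernel - 1L) * cumStride
  }
  setNames(ext, c("y", "x", "t"))
}

#' Initialize the weights of one stack
#'
#' Fan-in-scaled uniform initialization: entries of each kernel are drawn
#' uniformly on (-a, a) with a = 1/sqrt(fan-in); biases start at zero.
#'
#' @param spec a [StackSpec-class].
#' @param seed RNG seed.
#' @param head if FALSE, no prediction head (M, c) is allocated (slowness
#'   objective).
#' @return a [StackWeights-class]
#' @export
initStackWeights <- function(spec, seed = 1L, head = TRUE) {
  set.seed(seed)
  k <- spec@kernel; I <- spec@inChannels; J <- spec@convUnits
  aW <- 1 / sqrt(prod(k) * I)
  W <- array(runif(prod(k) * I * J, -aW, aW), dim = c(k, I, J))
  if (head) {
    aM <- 1 / sqrt(k[1] * k[2] * J)
    M <- array(runif(k[1] * k[2] * J * I, -aM, aM),
               dim = c(k[1], k[2], 1L, J, I))
    cc <- numeric(I)
  } else {
    M <- array(0, dim = c(0L, 0L, 0L, 0L, 0L))
    cc <- numeric(0)
  }
  new("StackWeights", W = W, b = numeric(J), M = M, c = cc)
}

.checkInputShape <- function(U, spec) {
  d <- dim(U)
  nm <- c("Y", "X", "T", "I")
  for (ax in 1:4) if (d[ax] != spec@inputShape[ax])
    stop(sprintf("input %s axis is %d but the spec requires %d",
                 nm[ax], d[ax], spec@inputShape[ax]))
  invisible(NULL)
}

#' Hidden activity of one stack (rectified strided valid convolution)
#'
#' H_j = relu(b_j + sum_i U_i * W_ji) with the spec's stride and no padding;
#' activities are therefore nonnegative everywhere.
#'
#' @param U input tensor (Y, X, T) or (Y, X, T, I).
#' @param spec a [StackSpec-class].
#' @param weights a [StackWeights-class].
#' @param preactivation if TRUE also return the pre-relu tensor (used by
#'   training).
#' @return hidden activity array (Y_h, X_h, T_h, J)
#' @export
convForward <- function(U, spec, weights, preactivation = FALSE) {
  U <- as4d(U)
  .checkInputShape(U, spec)
  A <- conv3d(U, weights@W, spec@stride)
  A <- sweep(A, 4, weights@b, "+")
  H <- relu(A)
  if (preactivation) list(H = H, A = A) else H
}

#' One-step-ahead prediction from hidden activity
#'
#' V^_k = c_k + sum_j H_j * M_kj with output kernels of temporal depth 1.
#' When the hidden layer was computed with spatial stride s > 1, H is first
#' dilated by inserting s-1 zeros between adjacent elements (fractionally
#' strided convolution), so the prediction recovers the input's spatial size
#' (Y_h - 1) * s + kernel for any stride, including s = 1. The head is linear,
#' so predictions are unbounded.
#'
#' @param H hidden activity from [convForward()] under the same spec.
#' @param spec,weights the stack's spec and weights.
#' @return prediction array (Y, X, T_h, K); time step t predicts the input
#'   frame one step after the last frame feeding hidden step t
#' @export
predictFuture <- function(H, spec, weights) {
  if (length(weights@M) == 0)
    stop("this stack has no prediction head (slowness objective)")
  hd <- hiddenLayerShape(spec)$shape
  if (!identical(unname(dim(H)), unname(as.integer(hd))))
    stop("H was not produced by convForward under this spec")
  V <- convTransposed(H, weights@M, spec@stride)
  expected <- (hd[1:2] - 1L) * spec@stride[1:2] + spec@kernel[1:2]
  if (!identical(unname(as.integer(expected)), unname(spec@inputShape[1:2])))
    stop(sprintf(
      "prediction is %dx%d but the input frame is %dx%d: stride/dilation mismatch",
      expected[1], expected[2], spec@inputShape[1], spec@inputShape[2]))
  sweep(V, 4, weights@c, "+")
}

#' Prediction loss: mean squared error plus L1 weight penalty
#'
#' mse = mean over every entry of (V^ - V)^2 (the squared-error sum divided by
#' N*K*X*Y*T); the penalty is lambda * (sum|W| + sum|M|).
#'
#' @param Vhat prediction tensor (or list of tensors, one per clip).
#' @param Vtarget target tensor(s), congruent with Vhat; the input one time
#'   step into the future.
#' @param weights optional [StackWeights-class] for the penalty term.
#' @param lambda L1 strength.
#' @return list with `mseTerm`, `l1Term`, `total`
#' @export
predictionLoss <- function(Vhat, Vtarget, weights = NULL, lambda = 0) {
  if (!is.list(Vhat)) { Vhat <- list(Vhat); Vtarget <- list(Vtarget) }
  stopifnot(length(Vhat) == length(Vtarget))
  sse <- 0; nel <- 0
  for (n in seq_along(Vhat)) {
    stopIfNaN(Vhat[[n]], Vtarget[[n]], what = "prediction/target")
    if (!identical(dim(Vhat[[n]]), dim(Vtarget[[n]])))
      stop("prediction and target are not congruent")
    sse <- sse + sum((Vhat[[n]] - Vtarget[[n]])^2)
    nel <- nel + length(Vhat[[n]])
  }
  mse <- sse / nel
  l1 <- if (is.null(weights)) 0 else lambda * (l1norm(weights@W) + l1norm(weights@M))
  list(mseTerm = mse, l1Term = l1, total = mse + l1)
}

#' Run a stimulus through the hierarchy
#'
#' Applies [convForward()] stack by stack and returns each stack's hidden
#' activity.
#'
#' @param model a [HierarchicalModel-class].
#' @param stimulus (Y, X, T) array at the stack-1 input resolution (any size
#'   admitting valid convolution).
#' @param upTo highest stack to evaluate.
#' @return list of hidden-activity arrays, one per stack
#' @export
forwardHierarchy <- function(model, stimulus, upTo = stackCount(model)) {
  out <- vector("list", upTo)
  U <- as4d(stimulus)
  for (z in seq_len(upTo)) {
    sp <- model@specs[[z]]
    d <- dim(U)
    if (any(d[1:3] < sp@kernel))
      stop(sprintf("stimulus too small for stack %d kernel", z))
    if (d[4] != sp@inChannels)
      stop(sprintf("channel axis is %d but stack %d expects %d",
                   d[4], z, sp@inChannels))
    A <- conv3d(U, model@weights[[z]]@W, sp@stride)
    A <- sweep(A, 4, model@weights[[z]]@b, "+")
    U <- relu(A)
    out[[z]] <- U
  }
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint records specs, weights, seeds, logs, objective and the
#' package/R versions for exact reload.
#'
#' @param model a [HierarchicalModel-class].
#' @param path file path.
#' @return `readModel` returns the model
#' @export
saveModel <- function(model, path) {
  saveRDS(list(model = model,
               versions = list(R = R.version.string,
                               package = as.character(utils::packageVersion(
                                 "TemporalPrediction")))),
          path)
  invisible(path)
}

#' @rdname saveModel
#' @export
readModel <- function(path) {
  obj <- readRDS(path)
  stopifnot(is(obj$model, "HierarchicalModel"))
  validObject(obj$model)
  obj$model
}
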