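# Stack-wise training: Adam on the per-stack objective (temporal prediction,
# present-input autoencoding, or slowness), gradients never crossing stack
# boundaries.

.adamInit <- function(weights) {
  zero <- function(x) { x[] <- 0; x }
  list(m = list(W = zero(weights@W), b = zero(weights@b),
                M = zero(weights@M), c = zero(weights@c)),
       v = list(W = zero(weights@W), b = zero(weights@b),
                M = zero(weights@M), c = zero(weights@c)),
       t = 0L)
}

.adamStep <- function(state, weights, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (p in names(grads)) {
    g <- grads[[p]]
    if (length(g) == 0L) next
    state$m[[p]] <- beta1 * state$m[[p]] + (1 - beta1) * g
    state$v[[p]] <- beta2 * state$v[[p]] + (1 - beta2) * g * g
    step <- lr * (state$m[[p]] / bc1) / (sqrt(state$v[[p]] / bc2) + eps)
    slot(weights, p) <- slot(weights, p) - step
  }
  list(state = state, weights = weights)
}

# split a ClipSet or a (list of arrays, split) pair into train/validation
# lists of 4D arrays
.asTrainingInput <- function(input, split = NULL) {
  if (is(input, "ClipSet")) {
    split <- input@split
    input <- input@clips
  }
  if (is.null(split)) stop("a train/validation split is required")
  input <- lapply(input, as4d)
  list(train = input[split == "train"], val = input[split == "validation"])
}

# forward + objective + gradients for one minibatch of one stack.
# Returns loss terms and parameter gradients (averaged over the batch, with
# the L1 subgradient included).
.stackBatchGrad <- function(batch, spec, weights, objective, lambda, lambda1,
                            gradient = TRUE) {
  kt <- spec@kernel[3]
  B <- length(batch)
  grads <- list(W = if (gradient) array(0, dim(weights@W)),
                b = if (gradient) numeric(length(weights@b)),
                M = if (gradient && length(weights@M)) array(0, dim(weights@M))
                    else numeric(0),
                c = if (gradient) numeric(length(weights@c)))
  dataTerm <- 0
  actTerm <- 0
  if (objective == "slowness")
    return(.slownessBatchGrad(batch, spec, weights, lambda, gradient))
  Wmat <- wAsMatrix(weights@W)
  Mt <- mTilde(weights@M)
  Mtmat <- wAsMatrix(Mt)
  kdHead <- as.integer(c(spec@kernel[1:2], 1L))
  for (U in batch) {
    fa <- convForward(U, spec, weights, preactivation = TRUE)
    H <- fa$H; A <- fa$A
    Vh <- convTransposed(H, weights@M, spec@stride)
    Vh <- sweep(Vh, 4, weights@c, "+")
    Th <- dim(H)[3]
    Tin <- dim(U)[3]
    if (objective == "prediction") {
      # hidden step t summarizes input frames t..t+kt-1 and predicts frame
      # t+kt; the last hidden step has no future target inside the clip
      tSel <- seq_len(Th - 1L)
      target <- U[, , (kt + 1L):Tin, , drop = FALSE]
    } else { # autoencoder: estimate the current (most recent) input frame
      tSel <- seq_len(Th)
      target <- U[, , kt:Tin, , drop = FALSE]
    }
    resid <- Vh[, , tSel, , drop = FALSE] - target
    stopIfNaN(resid, what = "prediction residual")
    nel <- length(resid)
    dataTerm <- dataTerm + sum(resid^2) / (nel * B)
    if (objective == "autoencoder")
      actTerm <- actTerm + sum(H) / (length(H) * B) # H >= 0 after relu
    if (!gradient) next
    dV <- array(0, dim(Vh))
    dV[, , tSel, ] <- 2 * resid / (nel * B)
    # head backward through the adjoint form: dMtilde = im2col(dV)' H,
    # dH = conv(dV, Mtilde)
    Hmat <- matrix(H, ncol = dim(H)[4])
    bw <- .cppConv3dBackward(as.numeric(dV), as.integer(dim(dV)), Mtmat,
                             kdHead, as.integer(spec@stride), Hmat, FALSE)
    grads$M <- grads$M + mTilde(array(bw$dW, dim(Mt)))
    grads$c <- grads$c + apply(dV, 4, sum)
    dHmat <- .cppConv3d(as.numeric(dV), as.integer(dim(dV)), Mtmat, kdHead,
                        as.integer(spec@stride))
    dH <- array(dHmat, dim(H))
    if (objective == "autoencoder")
      dH <- dH + (H > 0) / (length(H) * B) * lambda1
    dA <- dH * (A > 0)
    dAmat <- matrix(dA, ncol = dim(A)[4])
    bw2 <- .cppConv3dBackward(as.numeric(U), as.integer(dim(U)), Wmat,
                              as.integer(spec@kernel), as.integer(spec@stride),
                              dAmat, FALSE)
    grads$W <- grads$W + array(bw2$dW, dim(weights@W))
    grads$b <- grads$b + apply(dA, 4, sum)
  }
  if (gradient) {
    grads$W <- grads$W + lambda * sign(weights@W)
    if (length(grads$M)) grads$M <- grads$M + lambda * sign(weights@M)
  }
  l1 <- lambda * (l1norm(weights@W) + l1norm(weights@M))
  if (objective == "autoencoder") {
    total <- dataTerm + lambda1 * actTerm + l1
  } else total <- dataTerm + l1
  list(dataTerm = dataTerm, actTerm = actTerm, l1Term = l1, total = total,
       grads = grads)
}

#' Train one stack
#'
#' Minimizes the stack objective with Adam (beta1 = 0.9, beta2 = 0.999) over
#' minibatches of training clips, logging the training and validation data
#' term (prediction error for the prediction objective) at every iteration.
#' An iteration is one optimizer update step.
#'
#' @param input a [ClipSet-class], or a list of (Y, X, T, I) activity arrays
#'   with `split` supplied.
#' @param spec a [StackSpec-class].
#' @param seed RNG seed (weight initialization and batch sampling).
#' @param iterations optimizer steps (reference setting 1000).
#' @param batchSize minibatch size (reference setting 32).
#' @param objective "prediction", "autoencoder" or "slowness".
#' @param lambda L1 weight penalty; defaults to the spec's value.
#' @param lambda1 activity-sparsity strength (autoencoder only).
#' @param split train/validation labels when `input` is a plain list.
#' @param window iterations over which the final validation error is averaged
#'   to summarize predictive capacity (default 50).
#' @return list: `weights` ([StackWeights-class]), `log` (data.frame with
#'   iteration, trainError, valError), `valFinal` (mean validation data term
#'   over the final `window` iterations)
#' @export
trainStack <- function(input, spec, seed = 1L, iterations = 1000L,
                       batchSize = 32L, objective = c("prediction",
                                                      "autoencoder",
                                                      "slowness"),
                       lambda = spec@l1Strength, lambda1 = 1e-4,
                       split = NULL, window = 50L) {
  objective <- match.arg(objective)
  if (objective != "slowness" &&
      any((spec@inputShape[1:2] - spec@kernel[1:2]) %% spec@stride[1:2] != 0))
    stop("input minus kernel must be divisible by the stride so the ",
         "fractionally-strided head can match the input size")
  dat <- .asTrainingInput(input, split)
  if (length(dat$train) == 0L) stop("no training clips")
  weights <- initStackWeights(spec, seed = seed,
                              head = objective != "slowness")
  state <- .adamInit(weights)
  set.seed(childSeed(seed, 7L))
  nTrain <- length(dat$train)
  log <- data.frame(iteration = seq_len(iterations), trainError = NA_real_,
                    valError = NA_real_)
  for (it in seq_len(iterations)) {
    idx <- sample.int(nTrain, min(batchSize, nTrain),
                      replace = batchSize > nTrain)
    res <- .stackBatchGrad(dat$train[idx], spec, weights, objective, lambda,
                           lambda1)
    if (!is.finite(res$total))
      stop(sprintf("training diverged at iteration %d (loss %g)", it,
                   res$total))
    upd <- .adamStep(state, weights, res$grads, spec@learningRate)
    state <- upd$state; weights <- upd$weights
    log$trainError[it] <- res$dataTerm
    if (length(dat$val)) {
      val <- .stackBatchGrad(dat$val, spec, weights, objective, lambda,
                             lambda1, gradient = FALSE)
      log$valError[it] <- val$dataTerm
    }
  }
  valFinal <- mean(log$valError[max(1L, iterations - window + 1L):iterations])
  list(weights = weights, log = log, valFinal = valFinal)
}

#' Train a full hierarchy, stack by stack
#'
#' Greedy training: each stack is optimized independently starting from the
#' lowest; once trained, its hidden activity in response to every clip feeds
#' the next stack. Gradients never cross stack boundaries. For stacks above
#' the first, the L1 strength is selected over `lambdaGrid` by the lowest
#' validation prediction error (averaged over the final `window` iterations);
#' stack 1 uses its spec value directly.
#'
#' @param clipset a [ClipSet-class].
#' @param specs ordered list of [StackSpec-class].
#' @param seed RNG seed.
#' @param iterations,batchSize,window per-stack optimizer settings (see
#'   [trainStack()]).
#' @param objective "prediction", "autoencoder" or "slowness".
#' @param lambdaGrid numeric vector of candidate L1 strengths for stacks >= 2
#'   (default 10^-5, 10^-6, 10^-7); for the control objectives the spec values
#'   are used directly (selection by prediction error is not meaningful
#'   there).
#' @param lambda1 autoencoder activity-sparsity strength.
#' @param verbose print progress.
#' @return a [HierarchicalModel-class]
#' @export
trainHierarchy <- function(clipset, specs, seed = 1L, iterations = 1000L,
                           batchSize = 32L, objective = "prediction",
                           lambdaGrid = 10^c(-5, -6, -7), lambda1 = 1e-4,
                           window = 50L, verbose = FALSE) {
  dat <- .asTrainingInput(clipset)
  split <- c(rep("train", length(dat$train)),
             rep("validation", length(dat$val)))
  inputs <- c(dat$train, dat$val)
  weightsList <- list()
  logs <- list()
  for (z in seq_along(specs)) {
    sp <- specs[[z]]
    cands <- if (z == 1L || objective != "prediction") sp@l1Strength
             else lambdaGrid
    best <- NULL
    for (lam in cands) {
      fit <- trainStack(inputs, sp, seed = childSeed(seed, z),
                        iterations = iterations, batchSize = batchSize,
                        objective = objective, lambda = lam,
                        lambda1 = lambda1, split = split, window = window)
      if (verbose)
        message(sprintf("stack %d lambda %.2g: final val error %.5g", z, lam,
                        fit$valFinal))
      if (is.null(best) || (is.finite(fit$valFinal) &&
                            fit$valFinal < best$valFinal)) {
        best <- fit; best$lambda <- lam
      }
    }
    sp@l1Strength <- best$lambda
    specs[[z]] <- sp
    weightsList[[z]] <- best$weights
    logs[[z]] <- best$log
    if (z < length(specs)) {
      inputs <- lapply(inputs, function(U) convForward(U, sp, best$weights))
    }
  }
  new("HierarchicalModel", specs = specs, weights = weightsList,
      trainingLog = logs, objective = objective)
}

#' Train a control hierarchy (slowness or sparse autoencoder)
#'
#' Identical plumbing to [trainHierarchy()] with the loss swapped: the
#' slowness objective minimizes the mean-squared temporal derivative of
#' batch-normalized hidden activity subject to pairwise decorrelation; the
#' autoencoder objective reconstructs the current input with an L1 penalty on
#' hidden activity. Architectures and shapes are unchanged.
#'
#' @param clipset a [ClipSet-class].
#' @param objective "slowness" or "autoencoder".
#' @param specs ordered list of [StackSpec-class] (the spec l1Strength values
#'   are used; control-model penalties are chosen by RF appearance, not by
#'   prediction error).
#' @param seed,iterations,batchSize,lambda1,window as in [trainHierarchy()].
#' @param verbose print progress.
#' @return a [HierarchicalModel-class] with the objective recorded
#' @export
trainControlHierarchy <- function(clipset, objective = c("slowness",
                                                         "autoencoder"),
                                  specs, seed = 1L, iterations = 1000L,
                                  batchSize = 32L, lambda1 = 1e-4,
                                  window = 50L, verbose = FALSE) {
  objective <- match.arg(objective)
  trainHierarchy(clipset, specs, seed = seed, iterations = iterations,
                 batchSize = batchSize, objective = objective,
                 lambda1 = lambda1, window = window, verbose = verbose)
}
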