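# Alternative objectives and perturbation controls that isolate what the
# temporal-prediction objective contributes.

.bnEps <- 1e-5

# Batch-normalize hidden activity per channel over clips x space x time.
# Returns normalized list plus the statistics needed for the backward pass.
.batchNorm <- function(Hlist) {
  J <- dim(Hlist[[1]])[4]
  chan <- function(H, j) H[, , , j, drop = FALSE]
  mu <- numeric(J); sg <- numeric(J)
  for (j in seq_len(J)) {
    v <- unlist(lapply(Hlist, chan, j = j), use.names = FALSE)
    mu[j] <- mean(v)
    sg[j] <- sqrt(mean((v - mu[j])^2) + .bnEps)
  }
  Hn <- lapply(Hlist, function(H) {
    for (j in seq_len(J)) H[, , , j] <- (H[, , , j] - mu[j]) / sg[j]
    H
  })
  list(Hn = Hn, mu = mu, sigma = sg)
}

# adjoint of .batchNorm: given dL/dHn, return dL/dH
.batchNormBackward <- function(dHn, Hn, sigma) {
  J <- length(sigma)
  N <- length(Hn)
  out <- dHn
  for (j in seq_len(J)) {
    g <- unlist(lapply(dHn, function(x) x[, , , j]), use.names = FALSE)
    h <- unlist(lapply(Hn, function(x) x[, , , j]), use.names = FALSE)
    mg <- mean(g)
    mgh <- mean(g * h)
    for (n in seq_len(N))
      out[[n]][, , , j] <-
        (dHn[[n]][, , , j] - mg - Hn[[n]][, , , j] * mgh) / sigma[j]
  }
  out
}

# slowness objective core: temporal smoothness of batch-normalized activity
# plus mean |Pearson rho| over channel pairs (with a small uniform jitter on
# (0, 1e-4) added before the correlations to avoid zero-variance division).
# Returns the two data terms and, optionally, dL/dH (pre-normalization).
.slownessCore <- function(Hlist, gradient = FALSE, batchNorm = TRUE) {
  Hlist <- lapply(Hlist, as4d)
  d <- dim(Hlist[[1]])
  J <- d[4]
  if (J < 2L) stop("decorrelation term undefined for fewer than 2 channels")
  TH <- d[3]
  N <- length(Hlist)
  P <- d[1] * d[2] * TH
  if (batchNorm) {
    bn <- .batchNorm(Hlist)
    Hn <- bn$Hn
  } else {
    Hn <- Hlist
    bn <- list(sigma = rep(1, J))
  }
  ct <- 1 / (N * J * d[1] * d[2] * (TH - 1))
  crho <- 2 / (N * J * (J - 1))
  temporal <- 0
  decor <- 0
  dHn <- if (gradient) lapply(Hn, function(x) array(0, dim(x)))
  for (n in seq_len(N)) {
    H <- Hn[[n]]
    D <- H[, , -1L, , drop = FALSE] - H[, , -TH, , drop = FALSE]
    temporal <- temporal + ct * sum(D^2)
    G <- matrix(H, nrow = P, ncol = J) + runif(P * J, 0, 1e-4)
    Gc <- sweep(G, 2, colMeans(G))
    nrm <- sqrt(colSums(Gc^2))
    R <- crossprod(Gc) / outer(nrm, nrm)
    pairs <- which(upper.tri(R), arr.ind = TRUE)
    decor <- decor + crho * sum(abs(R[upper.tri(R)]))
    if (gradient) {
      dG <- matrix(0, P, J)
      for (p in seq_len(nrow(pairs))) {
        j <- pairs[p, 1]; jp <- pairs[p, 2]
        s <- sign(R[j, jp])
        dG[, j] <- dG[, j] + crho * s *
          (Gc[, jp] / (nrm[j] * nrm[jp]) - R[j, jp] * Gc[, j] / nrm[j]^2)
        dG[, jp] <- dG[, jp] + crho * s *
          (Gc[, j] / (nrm[j] * nrm[jp]) - R[j, jp] * Gc[, jp] / nrm[jp]^2)
      }
      dtmp <- array(0, dim(H))
      dtmp[, , -TH, ] <- dtmp[, , -TH, , drop = FALSE] - 2 * ct * D
      dtmp[, , -1L, ] <- dtmp[, , -1L, , drop = FALSE] + 2 * ct * D
      dHn[[n]] <- dtmp + array(dG, dim(H))
    }
  }
  dH <- NULL
  if (gradient) {
    dH <- if (batchNorm) .batchNormBackward(dHn, Hn, bn$sigma) else dHn
  }
  list(temporal = temporal, decor = decor, dH = dH)
}

#' Slowness objective on hidden activity
#'
#' Mean-squared difference between consecutive time steps of (batch-normalized)
#' hidden unit activity, plus the mean absolute Pearson correlation over all
#' unordered channel pairs (computed per clip over flattened space x time, a
#' small uniform jitter on (0, 1e-4) added first), plus an L1 penalty on the
#' input weights. There is no prediction head under this objective.
#'
#' @param H hidden activity: a (Y_h, X_h, T_h, J) array or a list of them (one
#'   per clip).
#' @param W optional input kernels for the weight penalty.
#' @param lambda L1 strength.
#' @param batchNorm normalize activity per channel over the batch first
#'   (default TRUE, as during training).
#' @param seed optional seed fixing the jitter draw.
#' @return list with `temporalTerm`, `decorrelationTerm`, `l1WeightTerm`,
#'   `total`
#' @export
slownessLoss <- function(H, W = NULL, lambda = 0, batchNorm = TRUE,
                         seed = NULL) {
  if (!is.list(H)) H <- list(H)
  if (!is.null(seed)) set.seed(seed)
  core <- .slownessCore(H, gradient = FALSE, batchNorm = batchNorm)
  l1 <- if (is.null(W)) 0 else lambda * l1norm(W)
  list(temporalTerm = core$temporal, decorrelationTerm = core$decor,
       l1WeightTerm = l1, total = core$temporal + core$decor + l1)
}

# minibatch gradient of the slowness objective for the generic trainer
.slownessBatchGrad <- function(batch, spec, weights, lambda, gradient = TRUE) {
  B <- length(batch)
  fw <- lapply(batch, convForward, spec = spec, weights = weights,
               preactivation = TRUE)
  core <- .slownessCore(lapply(fw, `[[`, "H"), gradient = gradient)
  grads <- list(W = NULL, b = NULL, M = numeric(0), c = numeric(0))
  if (gradient) {
    Wmat <- wAsMatrix(weights@W)
    grads$W <- array(0, dim(weights@W))
    grads$b <- numeric(length(weights@b))
    for (n in seq_len(B)) {
      dA <- core$dH[[n]] * (fw[[n]]$A > 0)
      bw <- .cppConv3dBackward(as.numeric(batch[[n]]),
                               as.integer(dim(batch[[n]])), Wmat,
                               as.integer(spec@kernel),
                               as.integer(spec@stride),
                               matrix(dA, ncol = dim(dA)[4]), FALSE)
      grads$W <- grads$W + array(bw$dW, dim(weights@W))
      grads$b <- grads$b + apply(dA, 4, sum)
    }
    grads$W <- grads$W + lambda * sign(weights@W)
  }
  l1 <- lambda * l1norm(weights@W)
  dataTerm <- core$temporal + core$decor
  list(dataTerm = dataTerm, actTerm = 0, l1Term = l1, total = dataTerm + l1,
       grads = grads)
}

#' Sparse-autoencoder objective
#'
#' Each stack estimates its input at the current time step (rather than the
#' future one): reconstruction mean squared error, an L1 penalty on hidden
#' activity (strength lambda1), and an L1 penalty on all weights (strength
#' lambda2).
#'
#' @param Uhat reconstruction tensor(s) (array or list, one per clip).
#' @param U input target tensor(s), congruent with Uhat.
#' @param H hidden activity tensor(s).
#' @param W,M input and output kernels (for the weight penalty); may be NULL.
#' @param lambda1 activity-sparsity strength.
#' @param lambda2 weight-sparsity strength.
#' @return list with `reconstructionTerm`, `activityL1Term`, `weightL1Term`,
#'   `total`
#' @export
autoencoderLoss <- function(Uhat, U, H, W = NULL, M = NULL, lambda1 = 0,
                            lambda2 = 0) {
  if (!is.list(Uhat)) { Uhat <- list(Uhat); U <- list(U); H <- list(H) }
  sse <- 0; nelV <- 0; sH <- 0; nelH <- 0
  for (n in seq_along(Uhat)) {
    stopIfNaN(Uhat[[n]], U[[n]], H[[n]], what = "autoencoder tensors")
    if (!identical(dim(Uhat[[n]]), dim(U[[n]])))
      stop("reconstruction and target are not congruent")
    sse <- sse + sum((Uhat[[n]] - U[[n]])^2); nelV <- nelV + length(U[[n]])
    sH <- sH + sum(abs(H[[n]])); nelH <- nelH + length(H[[n]])
  }
  rec <- sse / nelV
  act <- lambda1 * sH / nelH
  wt <- lambda2 * (if (is.null(W)) 0 else l1norm(W)) +
        lambda2 * (if (is.null(M)) 0 else l1norm(M))
  list(reconstructionTerm = rec, activityL1Term = act, weightL1Term = wt,
       total = rec + act + wt)
}

#' Shuffle input weights across space and time
#'
#' Within each stack, randomly permutes the entries of the input kernel set W
#' (across space, time, input channel and unit), preserving the weight value
#' multiset exactly; biases and output kernels are untouched. The permutations
#' are recorded in the returned model's "permutations" attribute so the
#' operation can be inverted bit-exactly.
#'
#' @param model a trained [HierarchicalModel-class].
#' @param seed RNG seed.
#' @return the perturbed model
#' @export
shuffleWeights <- function(model, seed = 1L) {
  set.seed(seed)
  perms <- vector("list", length(model@weights))
  for (z in seq_along(model@weights)) {
    W <- model@weights[[z]]@W
    perm <- sample.int(length(W))
    W[] <- W[perm]
    model@weights[[z]]@W <- W
    perms[[z]] <- perm
  }
  attr(model, "permutations") <- perms
  model
}

#' Invert a weight shuffle
#'
#' @param model a model produced by [shuffleWeights()] (its recorded
#'   permutations are used).
#' @return the model with original weight ordering restored
#' @export
unshuffleWeights <- function(model) {
  perms <- attr(model, "permutations")
  if (is.null(perms)) stop("model carries no recorded permutations")
  for (z in seq_along(model@weights)) {
    W <- model@weights[[z]]@W
    W[perms[[z]]] <- as.numeric(W)
    model@weights[[z]]@W <- W
  }
  attr(model, "permutations") <- NULL
  model
}
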