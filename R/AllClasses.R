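#' @import methods
#' @importFrom stats cor fft lm.fit coef prcomp plogis rnorm runif
#'   rpois sd var setNames
#' @importFrom Rcpp evalCpp
#' @useDynLib TemporalPrediction, .registration = TRUE
NULL

#' ClipSet: a collection of normalized movie clips
#'
#' Container for the training/validation movie material in the clip format the
#' models consume: each clip is a (height, width, frames) grayscale array,
#' normalized per clip to zero mean and unit standard deviation. Axis
#' convention throughout the package: (y, x, t), x increasing rightward and y
#' downward.
#'
#' @slot clips list of 3D numeric arrays, all of identical dimension.
#' @slot frameRate frames per second of the source material.
#' @slot split character vector, one of "train"/"validation" per clip.
#' @slot provenance scalar: "natural", "synthetic", "panned" or
#'   "frame_shuffled".
#' @slot seed integer seed recorded when randomness was involved (NA
#'   otherwise).
#' @export
setClass("ClipSet",
  representation(clips = "list", frameRate = "numeric", split = "character",
                 provenance = "character", seed = "integer"),
  prototype(frameRate = 25, provenance = "natural", seed = NA_integer_))

setValidity("ClipSet", function(object) {
  if (length(object@clips) == 0L) return("ClipSet contains no clips")
  d <- dim(object@clips[[1]])
  if (length(d) != 3L) return("clips must be 3D (y, x, t) arrays")
  same <- vapply(object@clips, function(cl) identical(dim(cl), d), logical(1))
  if (!all(same)) return("all clips must share one dimension")
  if (length(object@split) != length(object@clips))
    return("split must label every clip")
  if (!all(object@split %in% c("train", "validation")))
    return("split labels must be 'train' or 'validation'")
  TRUE
})

#' StackSpec: architecture of one stack
#'
#' Hyperparameters of a single single-hidden-layer spatiotemporal
#' convolutional stack: input shape, kernel size, stride, number of
#' convolutional hidden units, learning rate and L1 strength.
#'
#' @slot index position of the stack in the hierarchy (1-based).
#' @slot inChannels number of input channels I.
#' @slot convUnits number of convolutional hidden units J.
#' @slot kernel integer triple (y, x, t) kernel size.
#' @slot stride integer triple (y, x, t) convolution stride.
#' @slot learningRate Adam learning rate.
#' @slot l1Strength L1 regularization strength on the weights.
#' @slot inputShape integer quadruple (Y, X, T, I).
#' @export
setClass("StackSpec",
  representation(index = "integer", inChannels = "integer",
                 convUnits = "integer", kernel = "integer", stride = "integer",
                 learningRate = "numeric", l1Strength = "numeric",
                 inputShape = "integer"))

setValidity("StackSpec", function(object) {
  if (length(object@kernel) != 3L || length(object@stride) != 3L)
    return("kernel and stride must be integer triples (y, x, t)")
  if (length(object@inputShape) != 4L)
    return("inputShape must be (Y, X, T, I)")
  if (any(object@kernel > object@inputShape[1:3]))
    return("kernel exceeds input extent; valid convolution infeasible")
  if (object@inputShape[4] != object@inChannels)
    return("inputShape channel count disagrees with inChannels")
  if (any(object@stride < 1L) || any(object@kernel < 1L))
    return("kernel and stride entries must be positive")
  TRUE
})

#' StackWeights: learned parameters of one stack
#'
#' @slot W input kernels, 5D array (ky, kx, kt, I, J).
#' @slot b hidden biases, length J.
#' @slot M output (prediction-head) kernels, 5D array (ky, kx, 1, J, K).
#' @slot c output biases, length K.
#' @export
setClass("StackWeights",
  representation(W = "array", b = "numeric", M = "array", c = "numeric"))

setValidity("StackWeights", function(object) {
  if (length(dim(object@W)) != 5L) return("W must be 5D (ky, kx, kt, I, J)")
  if (length(object@M) > 0) {
    if (length(dim(object@M)) != 5L) return("M must be 5D (ky, kx, 1, J, K)")
    if (dim(object@M)[3] != 1L) return("output kernels must have temporal depth 1")
    if (dim(object@M)[4] != dim(object@W)[5])
      return("M hidden-channel count must equal number of hidden units J")
    if (length(object@c) != dim(object@M)[5])
      return("c must have one bias per output channel")
    if (!all(is.finite(object@M))) return("non-finite values in M")
  }
  if (length(object@b) != dim(object@W)[5])
    return("b must have one bias per hidden unit")
  if (!all(is.finite(object@W)) || !all(is.finite(object@b)) ||
      !all(is.finite(object@c)))
    return("non-finite values in weights")
  TRUE
})

#' HierarchicalModel: a trained stack of predictive networks
#'
#' @slot specs list of StackSpec, ordered from the lowest stack.
#' @slot weights list of StackWeights, parallel to specs.
#' @slot trainingLog list of per-stack data.frames (iteration, trainError,
#'   valError).
#' @slot objective "prediction", "slowness" or "autoencoder".
#' @export
setClass("HierarchicalModel",
  representation(specs = "list", weights = "list", trainingLog = "list",
                 objective = "character"),
  prototype(objective = "prediction"))

setValidity("HierarchicalModel", function(object) {
  if (length(object@specs) != length(object@weights))
    return("one StackWeights required per StackSpec")
  for (z in seq_along(object@specs)) {
    sp <- object@specs[[z]]
    if (!is(sp, "StackSpec")) return("specs must hold StackSpec objects")
    if (z > 1L) {
      below <- hiddenLayerShape(object@specs[[z - 1L]])$shape
      if (!identical(unname(sp@inputShape), unname(below)))
        return(sprintf("stack %d input shape must equal stack %d hidden shape",
                       z, z - 1L))
    }
  }
  TRUE
})

#' ReceptiveField: linear spatiotemporal filter of a model unit
#'
#' @slot weights 3D array (y, x, lag); most recent lag last.
#' @slot source "stack1_weights" or "reverse_correlation".
#' @slot unitId integer pair (stack, unit).
#' @slot defined FALSE when the estimate is undefined (e.g. a silent unit).
#' @export
setClass("ReceptiveField",
  representation(weights = "array", source = "character", unitId = "integer",
                 defined = "logical"),
  prototype(defined = TRUE))

#' GaborFit: parameters of a 2D Gabor fitted to an RF slice
#'
#' Parameterization: A * exp(-(x'/(2*sigmaX))^2 - (y'/(2*sigmaY))^2) *
#' cos(2*pi*f*x' + phi) with (x', y') the coordinates rotated by theta about
#' the center (x0, y0).
#'
#' @slot x0,y0 center (px). @slot sigmaX,sigmaY envelope widths (px).
#' @slot theta orientation (radians). @slot f spatial frequency (cycles/px).
#' @slot phi phase (radians). @slot A amplitude.
#' @slot fitCorrelation pixel-wise Pearson r between RF slice and fit.
#' @slot converged FALSE when no optimization start succeeded.
#' @export
setClass("GaborFit",
  representation(x0 = "numeric", y0 = "numeric", sigmaX = "numeric",
                 sigmaY = "numeric", theta = "numeric", f = "numeric",
                 phi = "numeric", A = "numeric", fitCorrelation = "numeric",
                 converged = "logical"),
  prototype(converged = TRUE))

setValidity("GaborFit", function(object) {
  if (object@converged && (object@sigmaX <= 0 || object@sigmaY <= 0))
    return("envelope widths must be positive")
  if (!is.na(object@fitCorrelation) &&
      (object@fitCorrelation < -1 - 1e-9 || object@fitCorrelation > 1 + 1e-9))
    return("fitCorrelation must lie in [-1, 1]")
  TRUE
})

#' ReadoutModel: linear-nonlinear Poisson readout from latent features
#'
#' Per neuron, predicted rate = softplus(m' h + d) from the reduced latent
#' feature vector h.
#'
#' @slot weights matrix (latent dim x neurons).
#' @slot bias numeric, one per neuron.
#' @slot lambdaRead L1 penalty used for the fit.
#' @slot log data.frame of per-epoch training loss.
#' @export
setClass("ReadoutModel",
  representation(weights = "matrix", bias = "numeric", lambdaRead = "numeric",
                 log = "data.frame"))

setValidity("ReadoutModel", function(object) {
  if (length(object@bias) != ncol(object@weights))
    return("one bias per neuron required")
  TRUE
})

## --- show methods -----------------------------------------------------------

setMethod("show", "ClipSet", function(object) {
  d <- dim(object@clips[[1]])
  cat(sprintf("ClipSet: %d clips of %dx%dx%d (%s), %d train / %d validation\n",
              length(object@clips), d[1], d[2], d[3], object@provenance,
              sum(object@split == "train"),
              sum(object@split == "validation")))
})

setMethod("show", "StackSpec", function(object) {
  cat(sprintf(
    "StackSpec %d: input %s, J=%d, kernel %s, stride %s, alpha=%g, lambda=%g\n",
    object@index, paste(object@inputShape, collapse = "x"), object@convUnits,
    paste(object@kernel, collapse = "x"), paste(object@stride, collapse = ","),
    object@learningRate, object@l1Strength))
})

setMethod("show", "HierarchicalModel", function(object) {
  cat(sprintf("HierarchicalModel (%s objective), %d stack(s)\n",
              object@objective, length(object@specs)))
  for (sp in object@specs) show(sp)
})

setMethod("show", "GaborFit", function(object) {
  cat(sprintf(
    "GaborFit: theta=%.1f deg, f=%.4f cyc/px, sigma=(%.2f, %.2f), r=%.3f%s\n",
    object@theta * 180 / pi, object@f, object@sigmaX, object@sigmaY,
    object@fitCorrelation, if (object@converged) "" else " (not converged)"))
})

setMethod("show", "ReadoutModel", function(object) {
  cat(sprintf("ReadoutModel: %d latent dims -> %d neurons, lambda=%g\n",
              nrow(object@weights), ncol(object@weights), object@lambdaRead))
})
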