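#' Number of stacks in a hierarchical model
#' @param object a HierarchicalModel
#' @return integer
#' @export
setGeneric("stackCount", function(object) standardGeneric("stackCount"))

#' @rdname stackCount
#' @export
setMethod("stackCount", "HierarchicalModel",
          function(object) length(object@specs))

#' Stack specifications of a model
#' @param object a HierarchicalModel
#' @return list of StackSpec
#' @export
setGeneric("stackSpecs", function(object) standardGeneric("stackSpecs"))

#' @rdname stackSpecs
#' @export
setMethod("stackSpecs", "HierarchicalModel", function(object) object@specs)

#' Learned weights of one stack
#' @param object a HierarchicalModel
#' @param stack stack index
#' @return a StackWeights
#' @export
setGeneric("stackWeights",
           function(object, stack = 1L) standardGeneric("stackWeights"))

#' @rdname stackWeights
#' @export
setMethod("stackWeights", "HierarchicalModel",
          function(object, stack = 1L) object@weights[[stack]])

#' Per-stack training logs
#' @param object a HierarchicalModel
#' @return list of data.frames (iteration, trainError, valError)
#' @export
setGeneric("trainingLog", function(object) standardGeneric("trainingLog"))

#' @rdname trainingLog
#' @export
setMethod("trainingLog", "HierarchicalModel", function(object) object@trainingLog)

#' Objective a model was trained with
#' @param object a HierarchicalModel
#' @return character scalar
#' @export
setGeneric("objective", function(object) standardGeneric("objective"))

#' @rdname objective
#' @export
setMethod("objective", "HierarchicalModel", function(object) object@objective)

#' Clips stored in a ClipSet
#' @param object a ClipSet
#' @param which "all" (default), "train" or "validation"
#' @return list of 3D arrays
#' @export
setGeneric("clips", function(object, which = "all") standardGeneric("clips"))

#' @rdname clips
#' @export
setMethod("clips", "ClipSet", function(object, which = "all") {
  if (which == "all") return(object@clips)
  object@clips[object@split == which]
})

#' Train/validation labels of a ClipSet
#' @param object a ClipSet
#' @return character vector
#' @export
setGeneric("clipSplit", function(object) standardGeneric("clipSplit"))

#' @rdname clipSplit
#' @export
setMethod("clipSplit", "ClipSet", function(object) object@split)

#' Number of clips
#' @param x a ClipSet
#' @export
setMethod("length", "ClipSet", function(x) length(x@clips))

#' Receptive-field tensor of a ReceptiveField object
#' @param object a ReceptiveField
#' @return 3D array (y, x, lag)
#' @export
setGeneric("rfWeights", function(object) standardGeneric("rfWeights"))

#' @rdname rfWeights
#' @export
setMethod("rfWeights", "ReceptiveField", function(object) object@weights)

#' Goodness of fit of a GaborFit
#' @param object a GaborFit
#' @return Pearson correlation between RF slice and fitted Gabor
#' @export
setGeneric("fitCorrelation", function(object) standardGeneric("fitCorrelation"))

#' @rdname fitCorrelation
#' @export
setMethod("fitCorrelation", "GaborFit", function(object) object@fitCorrelation)

#' Parameters of a GaborFit as a named vector
#' @param object a GaborFit
#' @return named numeric vector
#' @export
setGeneric("gaborParams", function(object) standardGeneric("gaborParams"))

#' @rdname gaborParams
#' @export
setMethod("gaborParams", "GaborFit", function(object) {
  c(x0 = object@x0, y0 = object@y0, sigmaX = object@sigmaX,
    sigmaY = object@sigmaY, theta = object@theta, f = object@f,
    phi = object@phi, A = object@A)
})

#' Readout weights
#' @param object a ReadoutModel
#' @return matrix (latent dim x neurons)
#' @export
setGeneric("readoutWeights", function(object) standardGeneric("readoutWeights"))

#' @rdname readoutWeights
#' @export
setMethod("readoutWeights", "ReadoutModel", function(object) object@weights)
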