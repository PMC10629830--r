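#' Desk-scale replication experiment
#'
#' Trains the two-stack miniature hierarchy on synthetic translating-texture
#' movies, characterizes every unit with the grating protocol, and repeats the
#' characterization for the two perturbation controls: the same model with its
#' input weights shuffled across space and time, and a model retrained on
#' frame-shuffled clips. Also computes the copy-last-frame prediction
#' baseline on the validation clips.
#'
#' @param seed master seed; all child seeds derive from it.
#' @param nClips number of synthetic clips (default 60, 90/10 split).
#' @param iterations,batchSize per-stack optimizer settings.
#' @param sfs,tfs grating search grid (reduced relative to the full protocol
#'   to keep the experiment desk-sized; directions stay on the 5-degree grid).
#' @param rcSamples binary-noise samples for stack-2 reverse correlation.
#' @param controls if FALSE, skip the two control models.
#' @param verbose print progress.
#' @return list with `clipset`, `model`, `char` (unit table), `baseline`
#'   (copy-last-frame validation MSE), `valError` (trained stack-1 validation
#'   prediction error, averaged over the final 50 iterations), and - when
#'   `controls` - `charShuffledWeights`, `charShuffledFrames`,
#'   `modelShuffledWeights`, `modelShuffledFrames`
#' @export
miniatureExperiment <- function(seed = 1L, nClips = 60L, iterations = 250L,
                                batchSize = 16L,
                                sfs = c(0.04, 0.08, 0.16, 0.3),
                                tfs = c(1.25, 5), rcSamples = 12000,
                                controls = TRUE, verbose = FALSE) {
  cs <- synthMovies(nClips, side = 64L, seed = childSeed(seed, 11L))
  specs <- miniatureSpecs()
  if (verbose) message("training standard model")
  model <- trainHierarchy(cs, specs, seed = childSeed(seed, 12L),
                          iterations = iterations, batchSize = batchSize,
                          lambdaGrid = 1e-6, verbose = verbose)
  kt <- specs[[1]]@kernel[3]
  baseline <- mean(vapply(clips(cs, "validation"), function(cl) {
    nt <- dim(cl)[3]
    mean((cl[, , (kt + 1):nt] - cl[, , kt:(nt - 1)])^2)
  }, numeric(1)))
  charOf <- function(m) characterizeModel(m, size = 64L, sfs = sfs, tfs = tfs,
                                          rcSamples = rcSamples,
                                          seed = childSeed(seed, 13L))
  if (verbose) message("characterizing standard model")
  char <- charOf(model)
  nlog <- nrow(model@trainingLog[[1]])
  out <- list(clipset = cs, model = model, char = char, baseline = baseline,
              valError = mean(model@trainingLog[[1]]$valError[
                max(1, nlog - 49):nlog]))
  if (controls) {
    if (verbose) message("weight-shuffle control")
    ws <- shuffleWeights(model, seed = childSeed(seed, 14L))
    out$modelShuffledWeights <- ws
    out$charShuffledWeights <- charOf(ws)
    if (verbose) message("frame-shuffle control (retraining)")
    fsClips <- frameShuffle(cs, seed = childSeed(seed, 15L))
    fs <- trainHierarchy(fsClips, specs, seed = childSeed(seed, 12L),
                         iterations = iterations, batchSize = batchSize,
                         lambdaGrid = 1e-6, verbose = verbose)
    out$modelShuffledFrames <- fs
    out$charShuffledFrames <- charOf(fs)
  }
  out
}

#' Count simple-cell-qualifying units in a characterization table
#'
#' Units classified simple by the grating protocol (Gabor fit correlation
#' > 0.4, circular variance < 0.9, modulation ratio > 1).
#'
#' @param char output of [characterizeModel()].
#' @return integer count
#' @export
countSimpleUnits <- function(char) sum(char$label == "simple")
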