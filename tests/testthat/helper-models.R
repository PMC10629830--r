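# Heavy fixtures built once per test run and shared across files.

.heavyCache <- new.env(parent = emptyenv())

# the desk-scale replication: miniature 2-stack model on synthetic translating
# movies, plus its weight-shuffled and frame-shuffled counterparts
getExperiment <- function() {
  if (is.null(.heavyCache$exp))
    .heavyCache$exp <- miniatureExperiment(seed = 42L)
  .heavyCache$exp
}
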