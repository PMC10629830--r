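---
title: "Hierarchical temporal prediction: model, probes, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical temporal prediction: model, probes, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Temporal prediction is the hypothesis that sensory neurons represent those
features of recent input that predict the immediate future, discarding the
rest. This package implements the hierarchical, convolutional form of that
idea: a stack is a single-hidden-layer 3D convolutional network whose hidden
activity is

    H_j = relu(b_j + sum_i U_i * W_ji)

(valid convolution over two spatial dimensions and time, stride `(s1, s2, s3)`),
and whose linear head predicts its own input one time step ahead,

    V^_k = c_k + sum_j H_j * M_kj,

with output kernels of temporal depth 1. Each stack is trained by Adam
(`beta1 = 0.9`, `beta2 = 0.999`, minibatches of 32) to minimize the mean
squared prediction error plus an L1 penalty `lambda * (sum|W| + sum|M|)`.
Stacks are trained greedily from the bottom: once a stack is trained, its
hidden activity in response to every clip becomes the next stack's input, and
gradients never cross stack boundaries. The predictive *signal* (the hidden
activity), not the prediction error, is what feeds forward — the structural
contrast with predictive-coding architectures.

The reference architecture (`referenceSpecs()`) takes 181x181x20 normalized
grayscale clips and stacks 50, 100, 200 and 400 convolutional units with
kernels 21x21x5 then 3x3x5; stack 1 uses spatial stride 10, learning rate
1e-2 and lambda 10^-4.5; the upper stacks use stride 1, learning rate 1e-4
and lambda selected on a 10^-5..10^-7 grid by validation prediction error.
Hidden-unit counts over spatial positions are 14,450 / 22,500 / 33,800 /
48,400, and receptive extents grow as 21x21x5, 41x41x9, 61x61x13, 81x81x17
(`hiddenLayerShape()`, `receptiveExtent()`).

### The fractionally-strided head

With spatial stride s > 1 the hidden layer is smaller than the input, so the
head first dilates `H` by inserting s-1 zeros between adjacent elements and
pads by kernel-1; valid convolution then returns exactly the input's spatial
size `(Y_h - 1) s + kernel`. We compute this without materializing the dilated
tensor, as the adjoint (`col2im`) of the corresponding strided convolution;
the two forms agree to machine precision (and at stride 1 reduce to a plain
full convolution), which the test suite asserts against an explicit
dilate-and-convolve oracle.

### Temporal alignment of the target

Output kernels have temporal depth 1, so a clip of T frames yields
T - T' + 1 prediction steps while only T - T' of them have a future frame
inside the clip: hidden step t summarizes frames t..t+T'-1 and predicts frame
t+T'. The loss therefore compares the first T - T' prediction steps with
input frames T'+1..T. The alternative (padding the target) would manufacture
data; dropping one step costs one frame of gradient signal per clip and
changes only a constant factor in the normalizer.

## Control objectives and perturbations

Two alternative objectives share `convForward()` and all shapes, isolating
what the prediction target contributes:

* **Sparse autoencoder** (`trainControlHierarchy(..., "autoencoder")`): the
  same head estimates the *current* input frame; the loss adds an L1 penalty
  `lambda1 * mean|H|` on hidden activity and `lambda2` on all weights. This
  objective is satisfiable with no temporal structure at all.
* **Slowness** (`trainControlHierarchy(..., "slowness")`): no head. The loss
  is the mean squared temporal derivative of hidden activity, after per-channel
  batch normalization over the minibatch, plus the mean absolute Pearson
  correlation over all unordered channel pairs (computed per clip over
  flattened space x time; a uniform jitter on (0, 1e-4) is added before the
  correlation to avoid zero-variance division, and is redrawn at every
  evaluation). The decorrelation term applies |.| to the scalar correlation
  — the natural reading of an L1 norm of a scalar. Batch statistics are those
  of the evaluated batch; there are no learned affine parameters.

Two perturbations: `shuffleWeights()` permutes every entry of each stack's
input kernels (value multiset preserved exactly, permutation recorded so the
operation inverts bit-exactly), and `frameShuffle()` permutes frame order
within clips before training. Both should — and in the shipped experiment do —
abolish structured receptive fields.

Because prediction error cannot rank control models (their losses are not
comparable), control-model penalties are plain configuration values chosen by
receptive-field appearance, the same procedure used for stack-1 lambda.

## The synthetic-movie generator

Natural wildlife footage is not redistributable, so `synthMovies()` generates
the statistics the models actually exploit: random-phase textures with a
radial amplitude spectrum falling as frequency^-1 (power f^-2, the classic
natural-image statistic), each clip rigidly translated at a per-clip velocity.
Defaults, fixed once: 20% of clips are still; the rest drift in a uniformly
random direction at 0.5-3 px/frame, the same range as the panning
augmentation used on natural footage; clips are 20 frames, normalized to zero
mean and unit variance, with a 90/10 train/validation split at clip
granularity. Translation is circular (the texture lives on a torus), which
keeps the motion exactly rigid with no border artifacts.

What the generator does *not* emulate: occlusion, independent object motion,
zoom and non-rigid deformation, luminance nonstationarity, photometric noise.
Consequently, passing tests show that the implementation reproduces the
training phenomenology under translating 1/f inputs — direction-selective
oriented units, complex-like units emerging in the second stack, controls
losing them — not that it reproduces every tuning statistic of models trained
on real footage.

## In-silico physiology

Stimuli live on the normalized-luminance scale (gray = 0, 40 ms frames).
Gratings are sinusoids of amplitude 3; plaids sum two amplitude-1.5
components whose motion directions straddle the pattern direction; binary
noise is iid +/-3.

Conventions that the literature leaves open, fixed here:

* **Response site.** Full-field stimuli make position immaterial up to phase,
  so a convolutional unit's response is the activity trace of the spatially
  central hidden unit of its channel, at all valid time steps (valid
  convolution already trims the onset transient; no extra window is dropped).
* **Optimal-grating search.** Directions 0-355 in 5 degree steps; spatial
  frequencies on 8 log steps over 0.02-0.4 cycles/px; temporal frequencies
  0.625-12.5 Hz; ties broken toward the lowest sf, then tf, then direction.
  The desk-scale experiment uses a reduced sf x tf grid (4 x 2) with the full
  direction grid, recorded in its results.
* **Metrics.** Circular variance uses angle doubling on the direction tuning
  curve. Orientation bandwidth smooths with a Hanning window of 13.5 degree
  half-width at half-height and takes half the angular distance between the
  70.7% crossings (interpolated; capped at 180, which is also the no-crossing
  value; the half-amplitude convention is available via `criterion = 0.5`).
  F1 comes from a least-squares sinusoid at the known stimulus frequency, not
  an FFT bin, so non-integer cycle counts are unbiased. DSI3 may exceed 1
  when the opposite direction is suppressed below the blank response.
* **Receptive fields.** Stack-1 kernels are the linear RF; deeper units are
  probed by reverse correlation with binary noise sized to the unit's
  receptive extent (so each stimulus yields exactly one hidden sample), the
  response-weighted stimulus average normalized by the summed response.
  Silent units are flagged undefined rather than returned as zeros.
* **Gabor fits** minimize squared error with multi-start Levenberg-Marquardt
  (orientation grid plus the slice's spectral peak, two frequencies, two
  phases); orientation is reported mod 180 degrees. Fit correlation > 0.4 is
  the simple-cell gate.
* **Exclusion.** Units whose optimal mean response is below 1% of their
  stack's maximum are excluded (0.1% population-wide is available for pooled
  analyses).
* **Pattern/component classification.** The plaid tuning curve is compared
  with the pattern prediction (the grating tuning) and the component
  prediction (grating tuning replicated at the two component directions) by
  partial correlation; Fisher-z statistics are compared at 1.28 (~90%
  confidence), with a descriptive peak count as fallback. The classification
  separation defaults to 120 degrees. No single criterion is canonical in the
  literature; this is the standard two-predictor construction.

## Neural-readout harness

`buildLatent()` concatenates model activity at t-1 and t-2 (a ~33-99 ms
latency span) and projects onto the leading 500 centered principal
components, the basis fit on cross-validation data only. `fitReadout()`
fits per-neuron rates softplus(m'h + d) by minimizing the negative Poisson
likelihood with an L1 penalty on m (Adam, batch 1024, learning rate 0.002,
300 epochs); `crossValidateLambda()` runs fivefold cross-validation over nine
log-spaced penalties (10^-6.5..10^-2.5) and refits at the winner.

Scores are CC_norm: the Pearson correlation between prediction and trial-mean
response divided by the noise ceiling CC_max. The ceiling uses the
signal-power construction from trial-to-trial variability,
`SP = (var(sum_trials) - sum(var_trial)) / (N (N-1))`,
`CC_max = sqrt(SP / var(trial mean))`; neurons with non-positive signal-power
estimates are flagged. Model comparison uses a paired bootstrap over neurons
(10,000 resamples; ties between resampled means counted as half a win, so
identical score vectors give exactly p = 0.5). `rescaleSearch()` repeats the
whole pipeline at 0.66x/1x/1.5x input scalings and per stack, reporting the
best. `synthNeurons()` plants a sparse softplus readout with Poisson trials
so the entire harness is testable with known ground truth; with ten trials
and a few counts per bin — the scale of the public V1 movie dataset — matched
features recover mean CC_norm above 0.9 while an independent random feature
bank scores near zero.

## Desk-scale experiment sizes

`miniatureExperiment()` is the package's own scaled-down replication: 60
synthetic 64x64x20 clips; stack 1 with 8 units, kernel 16x16x5, stride 6;
stack 2 with 16 units, kernel 3x3x5; lambda 1e-6; 250 Adam steps at batch 16.
The kernel is large relative to the frame (16/64, vs 21/181 in the reference
architecture) because smaller kernels learned envelopes too small to be
orientation-selective — the choice mirrors how the reference stack-1 penalty
is set by receptive-field appearance. Reverse correlation uses 12,000 noise
samples and the grating grid is 72 directions x 4 sf x 2 tf. On one CPU the
full experiment (standard model plus both controls) runs in 6-10 minutes.

## Known limitations

* No GPU path and no recurrent or feedback connections; training the
  reference 4-stack architecture on real footage is out of desk scale.
* Video container decoding is not included: `preprocessVideo()` accepts frame
  arrays or PNG/TIFF frame directories.
* Checkpoints and clip archives are RDS files, not HDF5.
* The slowness model implements gradient-trained slowness with decorrelation,
  not closed-form slow feature analysis.
* Pattern-selective units are rare at miniature scale; the plaid machinery is
  therefore validated with hand-built component/pattern oracle units rather
  than trained ones.
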