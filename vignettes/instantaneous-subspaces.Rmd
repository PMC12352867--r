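---
title: "Instantaneous subspaces: model, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Instantaneous subspaces: model, methods, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Premotor cortex (PM) neurons modulate their firing both when a monkey
executes a reach-grasp-manipulate (RGM) movement and when it observes the
same movement performed by another agent. At the population level, the
question is whether the *patterns of co-modulation* — the low-dimensional
subspaces in which the population's condition-dependent activity lives —
are shared between execution and observation, and how they evolve over the
course of a behavioral trial.

Because hand-movement population trajectories are complex, `instaspace`
follows the condition-dependent activity through a *time series of
instantaneous subspaces* rather than through a single subspace fitted to
the whole trial. At each 1 ms step of an event-aligned time base, the four
object condition means (sphere, button, coaxial cylinder, perpendicular
cylinder) form four points in the N-dimensional firing-rate space; PCA on
those four points (centered on their unweighted mean) yields a 3D basis
that captures all of their variance — the instantaneous condition-dependent
subspace. Everything else in the package is built on this object:

* **Principal angles** between instantaneous subspaces quantify how the
  condition-dependent subspace shifts through the trial, with a
  10-fold / 20-trials-per-object bootstrap for variability and a
  5000-draw random-subspace calibration for chance.
* **Trajectory segments** (100 ms, clipped at instruction onset I, go cue
  G, movement onset M, and hold H) are projected into instantaneous
  subspaces; their cumulative separation (CS) and their decodability (a
  small bidirectional LSTM classifying the four objects) quantify how much
  object information each subspace carries at each time.
* **Canonical correlation** (QR + SVD construction) aligns latent
  trajectory segments across sessions, contexts, and neuron classes, with
  a 500-iteration bootstrap over 20-trials-per-object resamples.

# Preprocessing model

Spike trains are binned at 1 ms (half-open bins `[t, t+1)`; an event-time
spike belongs to the bin at its right), smoothed with a Gaussian kernel
(sigma = 50 ms, truncated at 4 sigma, unit area), and square-root
transformed to stabilize variance across firing-rate levels. Each trial is
then clipped into four event-aligned snippets — I: [-500, +500) ms;
G: [-median delay, +median reaction/2); M: [-median reaction/2, +200);
H: [-200, +200) — and the snippets are concatenated, giving an axis of
`1600 + median delay + 2*round(median reaction / 2)` columns whose every
column is labelled by an (event, offset) pair.

Two choices deserve comment:

* **Session-level medians.** The snippet windows use delay/reaction
  medians pooled across objects, not per-object medians: the instantaneous
  subspace needs all four condition means at every column, which requires
  one common time base. Per-object medians are computed and reported by
  `compute_epoch_stats()` but do not affect clipping.
* **Shared time base across contexts.** Cross-context comparisons
  (principal angles, cross-projected decoding, CCA) require the execution
  and observation tensors to share `T` and the time map, so the pipeline
  reuses the execution context's epoch medians when aligning the
  observation context of the same session.

Smoothing near snippet edges uses real data where the trial extends beyond
the snippet and zeros otherwise, with no edge renormalization; the sharp
troughs in principal-angle courses within ~200 ms of a reference event are
a known imprint of the 50 ms kernel.

# Unit classification

Units are classed by two two-way ANOVAs (one per context) on spike counts
in eleven 200 ms task windows (before/after instruction onset and offset,
before/after go, before/after movement onset, before/after hold onset,
before hold end), with object (4 levels) and window (11 levels) as crossed
fixed factors and trials as replicates. A context is "modulated" when any
of the three p-values (object, period, interaction) falls below
alpha = 0.0083 (0.05/6: each unit gets six opportunities across its two
contexts). Modulated in both contexts = MN; execution only = AE;
observation only = AO; neither = NS. Under the null the per-context
flagging rate is `1 - (1 - alpha)^3 ~ 2.5%`, which the acceptance suite
verifies by simulation.

# The synthetic-session generator

`generate_session()` is the ground-truth engine: every downstream stage
has a test that recovers structure the generator planted. One session
context comprises 4 objects x `trials_per_object` successful trials in a
shuffled block design, with an initial hold (500-1000 ms), a 500 ms
instruction, a uniformly random 500-2000 ms delay, reaction and movement
epochs of a few hundred ms (Gaussian around 300/400 ms), a 1000 ms final
hold. Unit intensities are

```
lambda_n(t) = base_n + ci_gain_n * CI(t) + CD_n(object, t),   rectified at 0
```

with spikes drawn per 1 ms bin as an inhomogeneous Poisson process.
`CI(t)` is a multi-phasic envelope shared by all objects (bump after the
instruction, rise before movement, peak mid-movement, decay during hold).
`CD` lives in a planted orthonormal 3D basis that rotates progressively
(Givens rotation inside a fixed 6-dim frame, constant rate against
canonical event-anchored time, so the rotation angle at each behavioral
event is identical across trials); object identity selects a fixed
3-vector of latent weights (an irregular, non-equidistant tetrahedron)
times a fixed per-object temporal signature of the three channels. Mirror
(MN) units carry CD in both contexts — with the observation basis mixed so
that its principal-angle cosines against the execution basis equal
`context_overlap` — AE units carry CD and CI during execution only, AO
units CI during observation only, NS units neither. Observation CD
amplitude is lower than execution (8 vs 12 spikes/s by default), matching
the well-known weaker modulation during observation.

## Why the latent signatures look the way they do

Several structural choices in the generator exist because without them the
planted "shared latent relations" would be *unidentifiable in principle*,
making recovery tests vacuous:

* **Irregular weight tetrahedron and per-object temporal signatures.**
  Four mean-zero static points in 3D can be mapped onto *any* relabeling
  of themselves by a linear transform, so canonical correlation cannot
  distinguish true object correspondence from a permuted one when objects
  differ only in their mean positions. Real representations differ in
  their time courses too; the generator therefore gives each object's
  three latent channels a fixed two-frequency temporal signature (periods
  180-470 ms, shared across contexts), with a small constant part so that
  within any 100 ms window the objects differ mainly in their
  trajectories.
* **Phases fixed by a design search.** A 100 ms window smoothed at
  sigma = 50 ms supports only ~2-3 effective temporal degrees of freedom,
  so for unlucky phase combinations some relabeling of objects remains
  almost linearly realizable. The signature phases are fixed constants
  chosen (once, in a reduced noise-free model of the latent geometry) to
  keep the best derangement's achievable canonical correlation well below
  the true correspondence at the hold-segment windows of the default and
  test-scale configurations.
* **Signal latency.** The condition-dependent envelope starts ~60 ms
  after instruction onset (typical PM signal-related latency), ramps to
  half amplitude during the instruction epoch and to full amplitude
  between go cue and movement onset. Before the instruction there is no
  object information at all.
* **Rectification.** Intensities are rectified at zero before sampling;
  the default base rate (16 spikes/s) keeps the clipped fraction below
  0.5% so the planted geometry is essentially undistorted. Configurations
  with much larger CD amplitudes or lower base rates will bias the planted
  geometry at low rates.

What the generator does *not* emulate: refractoriness, adaptation, firing
correlations beyond the planted low-rank structure, error trials, eye
movements, non-Poisson count dispersion, and electrode artifacts. Passing
recovery tests on this generator therefore demonstrates the pipeline's
correctness, not the biological fidelity of any particular dataset.

# Numerical and statistical choices

* **Rank-deficient condition means** (fewer than 3 independent centered
  means, e.g. before any object information exists in a noise-free
  tensor) are completed to an orthonormal 3-frame with the lowest-index
  canonical directions orthogonalized against the span — deterministic
  and test-friendly. Singular values are clipped to [0, 1] before `acos`.
* **Projection centering.** `project_segment()` subtracts the
  condition-mean centroid of the target subspace's time step, so latent
  coordinates are displacements from the instantaneous centroid (the
  construction that the instantaneous PCA implies).
* **CCA centering.** For alignment, latent segments are additionally
  centered by the *time-resolved* across-object centroid before
  projection, and columns of `t(L)` are centered before QR so the
  canonical coefficients are correlations. Without the time-resolved
  centering, canonical correlation — being scale-free — latches onto the
  condition-independent drift common to all four objects, which is
  perfectly correlated across any two datasets and invariant to object
  relabeling, saturating both true and null alignments at CC1 ~ 1.
* **Permutation null for CCA** uses *derangements* of the four object
  labels. A relabeling with fixed points keeps part of the true
  correspondence, and for a single swapped pair there is almost always a
  latent direction blind to the swap (a smoothed 100 ms window has too
  few temporal degrees of freedom to forbid it), so transpositions
  produce CC1 ~ 1 on any data; only fixed-point-free relabelings
  constitute a genuine "no correspondence" null.
* **Decode-time subspaces are estimated from training trials only.** A
  basis fitted on all trials aligns with the realized noise separation of
  the four condition means, so even a session with *no* object-dependent
  modulation decodes well above chance when test trials participated in
  the basis estimate. `slide_decode()` therefore re-estimates the
  instantaneous basis per fold from the training split (its default);
  cross-projected decoding uses the explicitly supplied external series.
* **Train/test split.** The balanced resample (minimum per-object trial
  count, drawn with replacement) is split 40/60 at the level of distinct
  trials, stratified by object: duplicates follow their trial, so no
  trial appears on both sides and classes stay balanced on both sides.
* **LSTM training.** The 3-input, 20-hidden-units-per-direction
  bidirectional LSTM with a 4-class softmax is trained with Adam
  (learning rate 1e-3, batch 16, at most 100 epochs, early stop after 8
  epochs without a 1e-3 improvement of training loss); gradients are
  verified against numerical differentiation in the test suite. Latent
  inputs are z-scored with training-set statistics.
* **Session exclusion for CCA.** Any dataset in which some object has
  fewer successful trials than the resample size (20 by default) is
  excluded from CCA with an informative error.
* **Seeds.** A single global seed fans out into named substreams (one per
  stage, fold, and iteration) through a deterministic string hash, so any
  stage can be re-run in isolation with identical results.

# Known limitations and honest caveats

* Principal angles between a bootstrap (20-trial) subspace and the
  all-trial reference are biased upward by sampling noise, and the bias is
  shared across folds while the across-fold SD is small; bootstrap angle
  bands therefore sit above the noise-free (planted) course rather than
  covering it. The *shape* of the course — troughs at the reference event,
  progressive shifts — is recovered; its absolute level is not an
  unbiased estimate of the noise-free angle.
* Sliding-window decoding through a random or signal-free subspace is
  slightly above 1/4 whenever the segments themselves carry signal (a
  random 3-frame of a 50-dim space retains ~6% of it); chance bands
  estimated by `chance_decode()` inherit the same elevation, as in the
  original analyses.
* Cumulative separation depends on the firing-rate scale; it is reported
  in square-root-transformed rate units and is meaningful in comparisons
  (between subspaces, events, contexts) rather than absolutely.

# Problem sizes used by the tests

The unit tests run on reduced sessions (typically 20 units, 6-12 trials
per object, 500-1000 ms delays) chosen so the full suite exercises every
stage in a few minutes; the acceptance tests use the study-scale defaults
(50 units, 20 trials per object, 500-2000 ms delays) for the quantitative
criteria, with bootstrap iteration counts of 100-1000 where distributional
tails are needed. The end-to-end demonstration `run_demo()` uses 20 units
and 10 trials per object.
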