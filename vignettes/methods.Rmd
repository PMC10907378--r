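---
title: "Models, parameters and design choices in spiketrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in spiketrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`spiketrack` turns a pair of simultaneously acquired fluorescence movies
— a calcium-insensitive nuclear *anchor* channel and a cytoplasmic
calcium *activity* channel — into per-neuron spike rasters. This
vignette explains the models behind each stage, the parameters that
matter, what the synthetic generator does and does not emulate, and the
places where the design was genuinely open and a choice had to be made.

## Coordinate and data conventions

Positions are 0-based `(row, col)` with the origin at the top-left pixel
and pixel centers at integer coordinates; frames are 0-based. Movies are
`T x H x W` arrays of finite non-negative intensities in camera units.
Missing values in traces are explicit `NA`s, never zero: zero is a legal
intensity. Movies are stored per channel as separate grayscale
multi-page TIFF stacks (the cameras write separate streams); an internal
baseline TIFF reader/writer supports uncompressed 8/16-bit integer and
32/64-bit float stacks because no TIFF package is available in the
target runtime.

## Detection: à-trous wavelets with statistical thresholding

Nuclei are roundish bright spots on a noisy background. Each frame is
decomposed with the undecimated à-trous wavelet transform using the
B3-spline kernel `(1, 4, 6, 4, 1)/16` with holes of spacing `2^(j-1)` at
scale `j` and reflecting boundaries; the planes plus the final smooth
reconstruct the input exactly, which the tests assert to 1e-9. Spot
detection thresholds a single user-selected plane at `k · MAD/0.6745`
— a robust noise scale that ignores the sparse bright spots themselves —
then labels 8-connected supra-threshold components, discards components
below 5 px (the standard false-positive filter), and reports
intensity-weighted centers of mass computed on the raw frame.
Intensity weighting (rather than binary-mask centroids) localizes
asymmetric spots better, and positions are what tracking consumes.

Scoring is by *distance matching*: a predicted spot is a true positive
iff it can be paired one-to-one with a ground-truth spot closer than
`d`. We solve the pairing as a min-cost assignment with pairs at
distance `>= d` forbidden, which maximizes matches first and total
distance second; a greedy pairing can double-count in dense regions.
Calibration is a grid search over (scale, k) maximizing mean f1, with
ties broken toward smaller scale then smaller k. The two free
parameters are exactly the method's published knobs; the area filter
(5 px) and the matching distance default (d = 1 px) are the published
values.

The detector is pluggable: any function mapping a frame to
`frame_detections` can replace the wavelet detector (for example an
external star-convex deep-learning detector); the rest of the pipeline
depends only on that contract.

## Tracklet linking: conservative Kalman + assignment

The reference linker maintains a constant-velocity Kalman state per
track (white-acceleration process noise, default 1 px/frame²;
measurement noise 1 px). Each frame, predicted positions are matched to
detections by a min-cost one-to-one assignment (our own
shortest-augmenting-path solver, validated against brute force and an
independent library implementation) with a hard Euclidean gate
(`gate_radius_px`) widened by the Mahalanobis gate for uncertain,
coasting tracks. Unmatched tracks coast up to `max_missed_frames`
(default 5 — the typical run of missed detections after which
frame-to-frame trackers give up) and are then trimmed back to their last
detected frame. Interior coasted frames of re-acquired tracks keep their
predicted positions flagged `INTERPOLATED`: a track must have a defined
position at every covered frame. New tracks start with zero velocity and
inflated velocity covariance. Like the multi-hypothesis tracker this
stage stands in for, it is deliberately conservative: ending a tracklet
is cheap because stitching repairs identities globally.

## Stitching: TPS propagation + global assignment

When a tracklet ends, the animal keeps deforming; the stitcher estimates
where the lost nucleus *would* be. For each frame step `t -> t+1` a
thin-plate spline is fitted from the positions of all tracklets detected
at both frames (control points; smoothness `alpha = 10`, enough
regularization to absorb upstream linking errors), and the lost
position is pushed through step by step — forward from tracklet ends,
backward from tracklet starts. TPS with an unpenalized affine part
reproduces any affine motion exactly at every `alpha`, so rigid
translation costs nothing; the bending penalty only damps non-affine
flexing. Propagation truncates where fewer than `min_neighbors = 4`
control tracklets exist, and candidate links past the truncation are
forbidden rather than extrapolated without support.

The cost of linking tracklet *i* to a later tracklet *j* is the minimal
distance between *i*'s forward and *j*'s backward estimates over the
frames both cover; pairs that overlap in time or are separated by more
than `max_gap_frames = 50` are inadmissible (the cap bounds the
quadratic propagation cost; longer gaps are rarely uniquely
re-identifiable anyway). The global linking is a linear assignment in
which each unlinked endpoint (an end or a start) pays `eta/2`, so an
isolated tracklet pays the published non-linking cost `eta = 5 px` in
total and a link forms only when its cost is below `eta`. Chains merge
transitively; gap frames take a linear blend of the forward and backward
estimates, flagged `INTERPOLATED`. On instances small enough to
enumerate, the assignment provably attains the exhaustive optimum.

Per-frame-step iteration (rather than one TPS across the whole gap) was
chosen because the deformation is estimated locally in time, matching
how the propagation scheme is described; the per-step maps are shared
across all tracklets being propagated, which also makes the cost matrix
cheap.

## Calcium linking: the sub-ROI search

The activity channel is misaligned with the anchor by optics and by
biology (the indicator lives in the cytoplasm, the anchor in the
nucleus), non-uniformly across the field, so tracked nucleus positions
cannot simply be transferred. Around each tracked nucleus a
`25 x 25` px ROI is cut from the activity frame (edge-clipped ROIs pad
by replication). The patch is smoothed (Gaussian, σ = 1 px), multiplied
by a Gaussian prior centered on the nucleus (σ = 5 px), and the global
maximum is extracted 5 times with a 3-px suppression disc zeroed after
each hit. Two implementation details matter:

* The prior is for *ranking*, but it shrinks the argmax toward the
  nucleus by roughly `σ_prior² / (σ_prior² + σ_cell²)`; positions are
  therefore refined by a local center of mass of the prior-free smoothed
  patch, bounded by the suppression radius so the refinement can never
  wander onto a neighboring cell body. This recovers a constant channel
  offset to well under 1 px.
* Candidate *selection* on subsequent frames scores each candidate by
  its prior-weighted brightness times a Gaussian proximity to the
  previous calcium position (same σ as the nucleus prior). Selecting
  purely by distance to the previous position demonstrably locks onto a
  firing neighbor inside the ROI — exactly the crosstalk failure the
  sub-ROI method exists to prevent — whereas the brightness x
  center-proximity x history score keeps the tracked position on the
  correct cell body. The selected candidate is blended in with an
  exponential moving average (rate 0.5, halving the influence of any
  single wrong association).

Signals are disc means of radius 5 px (a pixel belongs to the disc iff
its center is within the Euclidean radius; border discs use only
in-bounds pixels): `calcium_raw` at the tracked calcium position in the
activity channel and `control` at the nucleus position in the anchor
channel.

## Signal processing

*Non-neuronal filtering.* Nematocyte-like cells hold a calcium plateau
for long periods; once activated their fluorescence variation is
imaging noise. Each raw calcium trace (mean-subtracted) is tested with
the D'Agostino–Pearson omnibus K² statistic; traces whose normality is
*rejected* (p < 0.05) look like spiking neurons and are kept. Flat or
too-short traces are flagged non-neuronal with p reported as 1. The
interactive review step of a GUI workflow is replaced by the `review.csv`
report plus config allow/deny lists (`signals$keep_ids`,
`signals$drop_ids`). Note that a plateau whose onset falls *inside* the
movie is strongly non-Gaussian and passes the filter — this is why a
review mechanism exists at all.

*Motion-artifact removal.* Axial motion changes intensity in both
channels identically, so a two-component FastICA (log-cosh nonlinearity,
symmetric decorrelation; tolerance 0.5 as published) is run on the
standardized (calcium, control) pair, 10 restarts with seeds derived
deterministically from the pipeline seed. Per run the calcium component
is the output more correlated with the raw calcium; across runs the
component *least* correlated with the control wins. The winner is
sign-fixed and rescaled to the raw trace's mean and variance because
downstream deconvolution needs a consistent amplitude scale. Degenerate
inputs (constant control) and non-convergence fall back to the raw
trace with a warning attribute.

*Detrending and smoothing.* A zero-phase (forward–backward) 5th-order
high-pass Butterworth with cutoff `1/100` cycles/frame removes baseline
drift without shifting spike times; a centered 5-frame rolling average
(shrinking windows at the edges) reduces noise. At the cutoff the
zero-phase filter passes `|H|² = 1/2` of the amplitude. Re-detrending
changes a broadband trace by well under 1% of its energy, but signals
concentrated right at the cutoff can lose up to ~1% more on a second
pass — the filter is sharp, not ideal.

## Spike inference

*Model.* Calcium fluorescence follows `c_t = g1 c_{t-1} + g2 c_{t-2} +
s_t` with non-negative spike intensities `s_t` — an AR(2) kernel with a
fast rise and slow decay pole. The default synthetic kernel uses poles
`exp(-1/3)` and `exp(-1/20)` (≈3-frame rise, ≈20-frame decay at 10 Hz, a
slow sensitive indicator).

*Parameter estimation.* The noise s.d. comes from the high-frequency
plateau of the periodogram (mean power over 0.25–0.5 cycles/frame). The
kernel poles are found by moment matching: the sample autocovariances at
lags 0–8 are fitted with the exact model of an AR(2) process observed in
white noise (noise inflates only lag 0), initialized from the modified
Yule–Walker equations (lags 3–8, which involve only noise-free lags) and
optimized over the two poles with the innovation and noise variances
profiled out. A parsimony rule collapses a spurious second pole when the
one-pole model fits within 5x of the two-pole optimum — on finite
samples of an AR(1)-like trace the second pole otherwise inflates, while
a genuine rise pole improves the fit by an order of magnitude. Plain
lag-1/2 Yule–Walker is exact on noiseless traces but collapses to AR(1)
under observation noise, which loses the rise time and lags every
inferred spike by 2–3 frames — the moment fit was adopted for exactly
this reason.

*Deconvolution.* The sparse non-negative problem
`min 0.5 ||y - K s - b||² + λ Σ s, s ≥ 0` (K the AR synthesis operator,
`b` a jointly fitted constant baseline) is solved by projected FISTA
with monotone restarts in compiled code; on 50–100-frame instances the
objective matches a generic box-constrained convex solver to better than
1e-4. With `sparsity_penalty = "auto"` the weight λ is found by
bisection so the residual matches `noise_sd · sqrt(T)` — the constrained
formulation. The deconvolution input is the ICA-corrected trace, *not*
the detrended/smoothed one: at firing rates where the inter-spike
interval approaches the 100-frame critical period, the zero-phase
high-pass creates undershoots that the non-negative AR model cannot
follow — the provably optimal fit to such a trace is nearly flat and
rejects genuine transients — and the rolling average flattens the very
PSD plateau the noise constraint needs. The jointly fitted baseline
absorbs the photobleaching trend instead (a few percent over a
1000-frame movie). The detrended and smoothed stages are still computed,
written, and used for review.

*Clustering and thresholding.* The spike-intensity trace is blurred
with a temporal Gaussian (σ = 5 frames), strict local maxima become
candidate events, candidates closer than 5 frames merge
(amplitude-weighted mean frame, summed amplitude), and events are kept
iff their blurred peak height reaches `max - 2·sd`. Two choices here
needed care. The threshold operates on each event's blurred *height*
(largest constituent after merging), not its merge-summed amplitude:
summing would inflate the per-cell maximum and discard genuine single
spikes. And `sd` is the population (ddof = 0) standard deviation over
the candidate event heights — which the worked
`{1.0, 0.9, 0.1} -> drop 0.1` example pins down — floored by the
population s.d. of the blurred trace itself: with near-equal genuine
events the event s.d. collapses and `max − 2 sd` would otherwise sit
just below the maximum and cut half of the real spikes. Events at trace
edges are kept; boundary contractions are real.

## The synthetic world

The generator emulates what the pipeline assumes and nothing more:

* **Body layout** — an elongated ellipse of cells with denser foot and
  head clusters. Cells are space-filling: with ~10 px diameter somata
  (Gaussian σ = 3 px, the disc-equivalent of the 5-px extraction radius
  the method prescribes) centers cannot sit closer than about one
  diameter, so the minimum spacing is 9 px; nuclei (σ = 2 px) are then
  close but resolvable, as in real images. An earlier, denser draft of
  this layout packed physically overlapping cells and was corrected on
  these grounds before the benchmark was frozen.
* **Motion** — a smooth time-varying displacement field (Gaussian-RBF
  interpolation of low-pass-filtered random control-point walks,
  amplitude 6 px), plus optional longitudinal contraction pulses toward
  the body center whose head-region inter-frame displacement exceeds
  typical nearest-neighbor spacing — the regime where tracking is known
  to fail.
* **Spikes** — per-neuron Bernoulli spiking at 0.1 Hz with a 10-frame
  (1 s) refractory period: calcium spikes here are discrete events
  seconds apart, which is also what the 5-frame merge window of the
  clustering assumes. Pure Poisson trains produce sub-blur bursts no
  σ = 5 clustering could resolve.
* **Channels** — anchor spots of constant amplitude; activity cell
  bodies with baseline 20 plus 30·c(t); additive Gaussian noise (σ = 4
  and 3 camera units); per-channel exponential bleaching applied to the
  whole frame; a global (3, 2) px channel offset with σ = 1 px per-cell
  jitter (the cytoplasm is not concentric with the nucleus).
* **Artifacts** — local multiplicative dips (depth 0.5, 3–10 frames,
  30–60 px radius) applied identically to both channels: axial motion
  does not darken the whole frame at once.
* **Nematocyte-like cells** — a single plateau onset, no discrete
  spikes.

Everything is deterministic given the seed. What the generator does
*not* emulate: volumetric (out-of-plane) structure, tentacle
kinematics, photon-physics camera noise, indicator nonlinearity and
saturation, and appearance variation between cells. A green test
therefore establishes that the algorithms behave as specified under the
stated statistical structure — not that they would reach the same
numbers on arbitrary real recordings.

## Numerical choices and degenerate inputs

* Assignment ties break deterministically (column scan order); all
  stochastic stages derive their seeds from the single pipeline seed,
  and a fixed seed gives byte-identical outputs.
* TPS fitting refuses collinear/coincident control points with an error
  suggesting an affine fallback; propagation truncates rather than
  extrapolate without support.
* Zero-variance traces are defined non-neuronal (p = 1): flat signals
  are exactly the class being removed.
* The wavelet threshold uses `>=` on positive coefficients; an all-zero
  frame yields zero detections rather than an error.
* Traces shorter than the Butterworth warm-up (3·(order+1) samples) or
  than 200 frames (AR estimation) are rejected with explicit errors;
  the pipeline skips spike inference for tracks shorter than
  `deconv$min_span_frames` and logs it.

## Known limitations

* The wavelet detector cannot split touching nuclei; in very dense
  regions recall drops, which is why the detector contract is pluggable.
* Clustering cannot resolve spikes closer than roughly twice the blur
  σ; bursts faster than ~1 Hz merge into single events.
* The adaptive threshold is permissive for cells with only one or two
  events (with two candidates it keeps both by construction).
* ICA removes only artifacts shared linearly between the channels;
  channel-specific artifacts pass through.
* Stitching assumes the body deformation is spatially smooth between
  frames; it has no appearance model, so two cells swapping positions
  within a gap are irrecoverable.
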