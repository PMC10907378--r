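# spiketrack

Tracking and spike estimation of single neurons in two-channel
fluorescence movies of soft, deforming animals.

## The problem

Recording every spike from every neuron in a behaving animal requires
three things that are each hard in a deformable organism such as *Hydra*:
(i) finding each neuron in every frame, (ii) keeping its identity as the
body writhes and contracts, and (iii) turning its calcium fluorescence
into discrete spike times. `spiketrack` implements an end-to-end pipeline
for dually labeled recordings — a calcium-insensitive nuclear **anchor**
channel used for detection and tracking, and a cytoplasmic calcium
**activity** channel read out at the tracked positions — plus a synthetic
movie generator with full ground truth, so that every stage is testable
without real data.

## The method

1. **Detection** — nuclei appear as bright spots; each anchor frame is
   decomposed with the undecimated à-trous wavelet transform (B3-spline
   kernel). The plane at scale *j* is thresholded at
   *k*·σ̂ with σ̂ = MAD/0.6745, 8-connected components below 5 px are
   discarded, and intensity-weighted centers of mass become detections.
   The two hyperparameters (scale, *k*) are calibrated by grid search
   against annotated frames using an f1-score under one-to-one
   center-of-mass matching at distance *d* (assignment solved exactly,
   not greedily).
2. **Tracklet linking** — a constant-velocity Kalman filter per track,
   gated distances to the current detections, and a per-frame min-cost
   assignment (Jonker–Volgenant). Conservative by design: ambiguous
   frames end tracklets rather than guess. The tracker sits behind a
   pluggable contract.
3. **Stitching** — when a tracklet ends prematurely, its position is
   propagated forward (and a later tracklet's backward) through per-frame
   thin-plate-spline deformations fitted to all tracklets detected on
   both sides of each frame step (smoothness α = 10). The stitch cost of
   a tracklet pair is the minimal distance between the forward and
   backward estimates; the global linking is a linear assignment with
   non-linking cost η = 5 px, and chains merge into full tracks with
   `INTERPOLATED` gap positions.
4. **Calcium linking** — the activity channel is misaligned with the
   anchor (optics plus nucleus/cytoplasm offset), so a 25×25 px ROI
   around each tracked nucleus is searched: Gaussian smoothing (σ = 1 px),
   a Gaussian positional prior (σ = 5 px), 5 iterated maxima with local
   suppression, candidate scoring by brightness × nucleus proximity ×
   previous-position proximity, and an exponential moving average
   (rate 0.5). Signals are disc means of radius 5 px.
5. **Signal processing** — plateau (nematocyte-like) cells are flagged by
   a D'Agostino–Pearson normality test (their post-activation variation
   is Gaussian imaging noise); shared-channel motion artifacts are
   removed by two-signal FastICA against the anchor control trace (best
   of 10 restarts, minimal correlation with the control); traces are
   detrended with a zero-phase 5th-order high-pass Butterworth filter
   (critical period 100 frames) and smoothed with a 5-frame rolling
   average.
6. **Spike inference** — constrained non-negative AR(2) deconvolution
   (sparse FOOPSI objective, projected FISTA, jointly fitted constant
   baseline, noise-constrained sparsity weight), then temporal Gaussian
   blurring (σ = 5 frames) of the spike intensities, local-maxima
   extraction, merging of events closer than 5 frames, and an adaptive
   per-cell amplitude threshold (max − 2 sd). Output is a raster of
   per-neuron event times.

## Worked example

```r
library(spiketrack)

cfg <- sim_config(n_neurons = 15, n_nematocytes = 2,
                  image_shape = c(140, 220), n_frames = 250,
                  min_spacing_px = 12, rng_seed = 42)
sim <- simulate_movie(cfg)

pc  <- pipeline_config(detection = list(scale = 1, k_sigma = 2), seed = 42)
res <- run_pipeline(sim$anchor, sim$activity, pc, out_dir = "run1")

rep <- evaluate_tracking(res$tracks, sim$truth, d_track = 3)
attr(rep, "mean_accuracy")
#> [1] 1
length(res$tracklets); length(res$tracks)
#> [1] 45
#> [1] 44
```

The run directory contains `detections.csv`, `tracklets.csv`,
`tracks.csv`, `traces.csv`, `review.csv` (the non-neuronal flags with
user-override column), `raster.csv`/`raster.png`, the resolved YAML
config and a log. A tracking accuracy of 1 means every ground-truth
trajectory was followed within 3 px for all 250 frames. On the reference
synthetic benchmark (50 neurons at the default density, T = 1000 at
10 Hz) the pipeline reaches mean tracking accuracy 1.00 and pooled
spike-time F1 0.835 at ±2 frames (see `tests/testthat/test-acceptance.R`,
which recomputes both).

A command-line front end mirrors this flow:

```sh
Rscript -e 'spiketrack::st_main()' simulate --config sim.yaml --out-dir sim/
Rscript -e 'spiketrack::st_main()' run --anchor sim/anchor.tif \
        --activity sim/activity.tif --out-dir run/
Rscript -e 'spiketrack::st_main()' evaluate --tracks run/tracks.csv \
        --truth-dir sim/
```

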