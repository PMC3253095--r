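---
title: "Trial-based preprocessing of awake-NHP fMRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial-based preprocessing of awake-NHP fMRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

High-field fMRI of awake nonhuman primates is acquired in short behavioural
trials: the head-fixed animal holds still for 10–30 s, then moves freely
(jaw, body, limbs) while it is rewarded, then initiates the next trial. The
head cannot move, but body and jaw movement perturbs the static field, and
at 7 T that perturbation is large enough to (a) ruin segmented-EPI volumes
with N/2 ghosting while the movement happens, (b) shift the apparent
position of the brain along the phase-encode axis between trials, and (c)
distort the image shape between trials. Less than half of the acquired
volumes carry usable task data, and the usable part is a *temporally
discontinuous* series — which breaks the assumptions of conventional
whole-session realignment and temporal filtering.

`trialfmri` implements the trial-oriented processing chain for this regime:
artefact QC and whole-trial selection, concatenation, a 2-step realignment,
gap-interpolated high-pass filtering, adaptive brain extraction, and a
five-method evaluation harness. This vignette records the models, the
parameter choices, and the numerical decisions behind each stage; every
empirical statement here is one the test suite or `scripts/acceptance.R`
computes.

# The simulator and its ground truth

All testing rests on `simulate_session()`, which assembles a session as

```
baseline x bias x (1 + activation + drift + run step) + noise
```

followed by per-volume geometric corruption and ghost injection. Its
components and defaults:

* **Phantom** (`make_phantom()`): an ellipsoidal brain (28% of the FOV per
  in-plane semi-axis, 30% in z) with 8% smooth internal texture
  (correlation length 3 mm) and a partial *lateral* shell of muscle-like
  tissue on the jaw side whose mean intensity is within ~10% of brain. The
  whole image receives a 1.1-voxel Gaussian rolloff emulating partial
  volume: real EPI has no binary tissue edges, and without the rolloff
  interpolation error at the edges dominates every registration and
  reslicing measurement. The muscle is confined in-plane because jaw
  musculature sits lateral to the brain; a closed polar cap would be
  6-connected to the brain through the top/bottom slices and no
  morphological step could separate the two.
* **Bias field**: multiplicative ramp `1 + strength (1 - d/d_max)` with
  distance from the coil centre, strength 1 by default (0.5–2 in the
  extraction tests) — the intensity gradient of small custom receive coils.
* **Activation**: two spherical blobs (4.5 mm radius) inside the brain,
  responding to the stimulation events with a peak amplitude of 2% of
  baseline. Events per trial: fixation from trial onset (6 s) and a 2 s
  stimulation at 6 s; regressors are the event boxcars convolved with the
  canonical double-gamma HRF. Noise is white Gaussian, sd 1% of mean brain
  baseline.
* **Drifts**: 2% linear per run plus a 1% cosine of 120 s period, and a 3%
  stepwise offset per run — the slow trends and between-run steps the 96 s
  filter and the per-run intercepts must absorb.
* **Within-trial motion**: a sinusoidal translation along the phase axis
  (amplitude 0.3 mm, period 7 s, phase reset at each trial's first volume)
  — respiration-scale apparent motion, deliberately pure 1-DOF because
  rotations and orthogonal shifts are physically impossible for a
  head-fixed animal within a trial.
* **Between-trial distortion**: a random 12-parameter affine per trial
  (defaults: ≤0.15 mm translation, ≤0.01 rad rotation, ≤1% scale, ≤0.005
  shear; the registration studies raise translation to one voxel), identity
  for the session's first trial. B0-induced apparent shifts and true
  position changes are not distinguished: both are geometric maps and the
  correction is identical.
* **Ghosts**: `volume + g · circshift(volume, FOV/2, phase_axis)` — the N/2
  ghost of segmented EPI — injected into 10% of inter-trial volumes at
  g = 0.3, plus every volume of configured "bad" trials (undetected
  in-trial movement).

Each component draws from its own seeded stream, so switching one artefact
off leaves the others bit-identical — the corrupted and clean versions of a
session differ only by the corruption, which makes residual-based oracles
exact. The ground truth records the masks, the injected shift per volume,
the injected affine per trial and the ghosted volume indices.

What the simulator does *not* emulate: spin physics (the ghost is a
one-parameter image-domain model), physiological noise structure beyond
drift + white noise, eye movements, k-space effects of motion during a
readout, and temporally autocorrelated noise. Passing tests therefore
demonstrate correct *geometry, bookkeeping and inference mechanics* under
the modelled artefact phenomenology — not performance on any real dataset.

# QC and trial selection

`ghost_ratio()` is mean intensity over a brain region divided by the mean
over a ghost region (stabilised by `eps = 1e-12 · max`); the default ghost
region (`default_ghost_roi()`) is the brain mask circularly shifted by half
the FOV along the phase axis, minus the brain — exactly where the N/2 ghost
of the brain lands. `com_shift()` is the intensity-weighted centroid in mm
relative to a reference volume.

`auto_flag()` flags a volume when its ghost ratio falls below threshold or
its CoM deviates from the *run median* CoM by more than `com_threshold_mm`.
Two robustness choices matter here:

* The adaptive ratio threshold is `median − 3·max(MAD, 0.02·median)` per
  run. ROI means average thousands of voxels, so their run-to-run spread is
  far below anything physically meaningful; the 2%-of-median floor stops
  the MAD from flagging sub-percent wobble, while a visible ghost
  (g ≥ 0.2) drops the ratio by tens of percent.
* CoM deviation is measured from the run median rather than from the
  nominal reference volume, because the reference (the run's first volume)
  is an inter-trial volume and may itself be ghosted; the median-centred
  rule reduces to the reference-relative one when the reference is clean.

The default `com_threshold_mm` is 0.3 for standalone QC. Inside the
method-comparison harness (`method_config()`) it defaults to 2 mm: there,
fraction-of-a-voxel between-trial displacements are exactly what the
2-step realignment corrects — rejecting them would leave no data — whereas
ghost-scale centroid excursions are an order of magnitude larger.

`reject_trials()` marks any trial containing a flagged volume
`auto_flagged`; single-volume excision is deliberately not offered (the
movement that degrades one volume perturbs the field for its whole trial).
Manual overrides (a `trial_id`/`status` table) are applied last and win in
both directions, keeping the unavoidable subjectivity of visual inspection
scriptable and auditable. `concatenate()` keeps exactly the accepted
trials' volumes and records the kept/removed partition with original
acquisition times — the backbone every later stage uses.

# 2-step realignment

Registration minimises the mean squared intensity difference (MSD) after
Gaussian pre-smoothing (FWHM 2 voxels) of both images — the simplest
same-modality cost. Numerical decisions:

* **Cost evaluation** uses trilinear interpolation on the smoothed images
  and scores a *fixed interior margin* of the output grid (2 voxels
  in-plane, 1 slice in z); samples mapped outside the field of view
  compare against background. The scored set must not depend on the
  parameters: a "valid samples only" cost lets the optimiser push
  high-error edge voxels out of view (we measured a z-scale bias of ~0.06
  from exactly this), while scoring everything penalises information that
  was genuinely lost at the edges.
* **1-DOF search** (`estimate_shift_1d()`): a half-voxel coarse scan over a
  ±5 voxel bracket followed by golden-section refinement to 0.01 voxel;
  the MSD profile need not be unimodal over the full bracket. Positive
  shift = the object moved toward increasing voxel index. Flat images are
  a degenerate-input error.
* **Affine estimation** (`estimate_affine()`): staged Nelder–Mead —
  translations, then + rotations, then all 12 parameters — warm-started
  stage to stage, with parameter scaling (mm for translations, 0.02 for
  the rest) and iteration budgets (150/200/400). Budget exhaustion returns
  the best-so-far parameters flagged `converged = FALSE`. The transform
  maps moving to reference coordinates about the volume centre,
  factorised `T·R·Z·S` with intrinsic rotations about x, then y, then z
  and unit upper-triangular shears; the parameterisation is stated once
  and asserted everywhere, since only the parameter *names* are standard.
  Note the sign relation: the affine's translation is the negative of the
  1-DOF object shift.
* **Composition** (`compose_and_reslice()`): each volume is resampled
  exactly once through `x -> M_trial^{-1} x + s_vol e_phase` with cubic
  (Catmull–Rom) interpolation, zero outside the FOV. The test suite
  verifies both that the composed reslice undoes the injected corruption
  (interior residual, noise-free, below 2% of baseline) and that it beats
  the sequential shift-reslice-then-affine-reslice alternative — the
  single-interpolation argument for keeping parameters rather than
  reslicing early.

`realign_rigid6()` provides the conventional whole-series 6-DOF baseline
(every volume to the first, warm-started from its predecessor) used by
methods 1–3.

# Gap-interpolated high-pass filtering

The filter is a projection onto the complement of the non-constant
discrete-cosine vectors with period above the cutoff
(`K = floor(2·N·TR/cutoff)` per run): zero phase, exactly idempotent,
linear, and the DC term is retained (between-run steps are handled as
session intercepts in the GLM, not by the filter). A cutoff at or below
2·TR leaves no basis vectors and warns.

`interpolate_gaps()` restores each run's even time grid before filtering:
for each gap between consecutive accepted trials, anchors are the
voxelwise mean of the preceding trial's last two volumes and of the
following trial's first two, each placed at the *midpoint of the averaged
volumes' acquisition times* (the natural location of an average; the
choice is asserted by a hand-computed example: anchors (0.5 s, 1) and
(4.5 s, 5) fill a TR-1 gap with 2.5 and 3.5). Leading/trailing gaps extend
the nearest anchor as a constant — bounded behaviour for an edge case the
procedure leaves open. Trials of one volume anchor with that volume.
`drop_interpolated()` then discards the synthetic samples, and on gap-free
input the whole chain is bit-equal to the plain filter.

Default cutoff 96 s for the gap filter; the model-side filter applied in
every method of the comparison harness uses 128 s. Both are configurable.

# Adaptive brain extraction

EPI at high field with a small receive coil gives brain and jaw muscle
similar intensities plus a strong spatial intensity gradient, so plain
thresholding cannot separate them. `radial_weight()` multiplies the
temporal mean image by `exp(-(d/sigma)^2)` with
`sigma = d_max/(1 + strength)` (`d_max` = distance from the crosshair to
the farthest corner, mm): intensity is preserved at the crosshair and
decays with distance, pushing peripheral muscle below threshold. The
threshold is a fraction of the *weighted image's maximum*, making the
slider scale-free. "Filling from inside" is realised as 1-voxel binary
closing, interior hole filling (background components not touching the
array border) and selection of the component containing — or nearest to —
the crosshair; a per-slice 2D mode does the same in-plane. The mask is
applied to the original intensities, so the radial weight (an artificial
bias field) never enters the analysed data; extraction runs on the mean
image only, which requires prior realignment and makes the mask invariant
to volume order.

Defaults `strength = 1`, `threshold_frac = 0.28` were calibrated once on
the phantom across bias strengths 0.5–2 (the interactive workflow this
replaces tunes the same two sliders per dataset by eye);
`grid_search_params()` automates that tuning, scoring candidate masks by
mean boundary gradient times compactness, with deterministic first-wins
tie-breaking.

# GLM and the five-method comparison

Regressors are built per run on a fine grid (TR/16), boxcars convolved
with the canonical double-gamma HRF (peak delay 6 s, undershoot 16 s, unit
dispersions, undershoot ratio 1/6, 32 s support, peak-normalised), sampled
at volume acquisition times — always *before* concatenation, with
`select_regressor_rows()` applying the identical row selection afterwards
so model and data stay aligned. The GLM is voxelwise OLS with grand-mean
scaling to 100, per-run intercepts, and `t = c'b / sqrt(s² c'(X'X)⁻¹c)`;
rank-deficient designs fall back to a pseudo-inverse with a warning, and
voxels with residual variance below `1e-12` of the grand mean report t = 0
with a degenerate flag. No AR(1) prewhitening is applied — a documented
limitation; the simulated noise is white, so the tests' inference is
valid, but on real data the t-values would be optimistic.

The harness runs five analyses sharing smoothing (2 mm FWHM), the 128 s
model filter (applied to data and condition regressors; one-hot artefact
columns and intercepts stay unfiltered so an artefact column still zeroes
its volume's residual exactly), grand-mean scaling and the T = 3.11
counting threshold: (1) rigid whole-series realignment only; (2) + one-hot
artefact regressors for every flagged volume, every volume of a flagged
trial, and all inter-trial volumes; (3) concatenation + rigid realignment;
(4) concatenation + 2-step realignment; (5) method 4 + the 96 s gap
filter. The acceptance suite checks the ordering property (method 5 above
method 1 and at least matching 2–4 on the corrupted default session,
seed-averaged) and that with *all* disturbances off — including drift and
the run step, which are corruptions in their own right — the five methods
agree on suprathreshold counts within 10%.

# Test design and problem sizes

The unit and acceptance tests run on reduced sessions chosen to keep the
full suite at a few minutes on one CPU while preserving every mechanism:
typically 40×40×9 voxels at 1.5×1.5×2 mm, 2 runs × 100 volumes at TR 2 s
with 4 trials of 12 volumes per run (registration studies: 32×32×11, one
run; extraction: 48×48×11; the trial-bookkeeping study: 62 trials across 2
runs of 300 volumes). Seed counts are 2–8 per study in the test suite and
3–8 in `scripts/acceptance.R`. Detection sensitivity/specificity is
assessed under ghost-only corruption, because with motion enabled the CoM
criterion correctly flags genuinely moved volumes, which a contrast
against ghost-only ground truth would mis-score as false positives.

# Known limitations

* OLS without prewhitening (above).
* The ghost model is a single-parameter image-domain approximation of
  inter-shot inconsistency.
* The affine estimator's z-scale is weakly identified on thin slabs
  (~10 slices): its single-case error can reach ~0.02 even though median
  errors stay well below 0.01.
* Thresholds for the QC criteria are robust defaults, not learned; on real
  data they are meant to be inspected and overridden per session, as the
  override-table mechanism provides.
* No slice-timing correction, field-map/navigator alternatives, nonlinear
  warping, template normalisation or group analysis.
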