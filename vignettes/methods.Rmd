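---
title: "Parcellating functional nodes and boundaries: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parcellating functional nodes and boundaries: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What this package computes

`nodebound` implements two complementary subject-level parcellations of
resting-state fMRI, and the machinery to ask whether an intervention (such
as repetitive transcranial magnetic stimulation) changed them:

1. **Node-density maps** (snowballing). Starting from a grid of seed
   spheres, each seed's whole-brain correlation map is thresholded at
   *r* > 0.3, clustered, and each cluster's local maxima are recorded as
   peaks; the peaks become the next zone's seeds. Over three zones, the
   per-voxel count of peak identifications forms a node-density map whose
   hotspots are the cores ("hubs") of functional regions.

2. **Boundary-gradient maps**. On a coarse analysis grid, every voxel's
   temporal-correlation map is compared with every other voxel's by
   spatial correlation, giving an N × N similarity matrix. Each row,
   scattered back into the brain, is a similarity map; the average of the
   spatial-gradient magnitudes of all N similarity maps is high where
   whole-brain connectivity profiles change abruptly — the putative
   boundaries between functional regions.

Around these sit: group spatial ICA of an independent session set, from
which a **node mask** (per-component percentile overlay) and a
**boundary mask** (watershed-style component-intersection descent) are
built; **sham correction** (real-visit map minus sham-visit map, per
subject and interval); and a **linear SVM** (one-versus-one, C = 1) with
leave-k-subject-out cross-validation, mask-threshold sweeps, subject-level
bootstrap confidence intervals, and a head-motion control based on mean
framewise displacement.

Because the human dataset this design emulates is not redistributable, the
package carries a first-class synthetic-data module. Every quantitative
claim the test suite makes is made against that phantom, whose ground
truth is known by construction.

## The phantom

`make_phantom()` tiles an ellipsoidal brain mask with K Gaussian network
weight maps whose centres come from k-means on the in-mask coordinates.
The blob width is `sigma_scale` (default 0.35) times the expected
centre-to-centre spacing: wide enough that neighbouring networks overlap
at their rims (transition zones about one to three voxels thick), narrow
enough that each network remains individually identifiable to spatial ICA
— with substantially wider blobs, ICA recovers one-versus-rest contrasts
instead of the networks themselves.

Ground truth: each network's weight maximum is a **node voxel**; a voxel
whose *second*-strongest network weight still reaches `support_floor`
(default 0.15) lies where two supports overlap and is a **boundary voxel**;
voxels with a dominant network (strongest weight ≥ 0.6, runner-up ≤ 30% of
it) are **core voxels**. Far-rim voxels where every network is negligible
are not boundaries — a transition of nothing into nothing.

Subjects differ by a smooth random displacement field (amplitude 1 voxel
by default) applied to the network maps; a subject's layout is identical
across all of that subject's sessions, which is exactly the structure the
subject-specificity test checks (within-subject map correlation must
exceed between-subject correlation).

Session time series are `Σ_k w_k(v)·s_k(t)` plus nuisance signals and
white noise. The latent `s_k` are unit-variance Gaussian signals shaped in
the frequency domain to the 0.01–0.1 Hz band (hard edges; out-of-band
power < 5%). Nuisance proxies (two WM/CSF-like smooth signals with random
loadings, one global signal with uniform loading, amplitude 0.3) and white
noise with `noise_sd = 1` complete the model: at a network core roughly
half of the voxel variance is network signal, which is on the generous end
of what task-free BOLD offers but keeps the desk-scale problems honest.
Head motion is a random walk on the six rigid-body parameters
(translations 0.02 mm per frame, rotations a hundredth of that), and is
deliberately independent of condition so the motion control must sit at
chance.

**Condition effects.** `effect_spec()` injects a modulation into
real-visit sessions of chosen intervals at chosen voxels.
`coupling_change` scales the dominant network's weight by `1 + δ`.
`boundary_blur` is a cross-fade: the voxel's own-network coupling is
scaled by `1 − δ` while the locally second-strongest network's signal is
admixed at amplitude `δ·(w_own + w_nb)`; at δ = 1 the voxel has fully
adopted its neighbour, i.e. the border has effectively moved across it.
This convention was chosen because milder ones (admixture proportional to
the local weight alone) produce boundary-map changes an order of magnitude
below the similarity matrix's sampling noise — a "strong effect" that no
method could recover is not a useful top of a power curve. δ = 0 is an
exact null: real and sham sessions are drawn from identical distributions.

## What the phantom does not emulate

No physiological noise (cardiac/respiratory aliasing), no scanner drift,
no susceptibility distortion, no spatial autocorrelation of the noise (the
generator has no point-spread function), no registration error beyond the
smooth jitter field, and real resting-state networks are neither Gaussian
blobs nor static over a session. Passing tests therefore demonstrate that
the pipeline's machinery is correct and sensitive under a faithful
statistical idealization — not that any specific empirical accuracy on
scanner data is reproduced.

## Numerical and design choices that matter

* **Detrend + band-pass as one projection.** Removing a linear trend and
  keeping a frequency band do not commute; applied naively the pair is not
  idempotent (repeated cleaning keeps changing the data, by 3–8% in our
  measurements). `detrend_bandpass()` instead applies the closed-form
  orthogonal projection onto the intersection (band-limited AND
  trend-free), `P = F − F Q (QᵀF Q)⁻¹ QᵀF`, with hard band edges so `F`
  itself is a projection. A cosine edge taper was considered and dropped:
  any gain strictly between 0 and 1 keeps attenuating its bins on every
  application.

* **Framewise displacement** uses the summed-absolute-differences form
  with a 50 mm rotation radius, the field's common convention and the one
  under which the 0.5 mm mean-FD cutoff is customarily quoted.

* **Similarity with self-exclusion.** The spatial correlation between two
  voxels' temporal-correlation maps excludes both self-correlation
  entries (each is a trivial 1.0). The exclusion is applied in closed form
  from the full-vector sums, so the N × N matrix costs two matrix products
  rather than an N³ loop, and rows can be produced in blocks
  (`chunk_size`) so the full matrix is never materialized — the average
  gradient map streams over row blocks.

* **Degenerate similarity pairs.** If both excluded vectors are constant
  (uniform connectivity), Pearson correlation is undefined; two constant
  and equal maps count as identical (similarity 1), anything else 0. This
  makes "all voxels share one time series ⇒ boundary map is zero" hold
  exactly.

* **Gradients** are central differences in map-units per mm with
  one-sided fallback at mask edges; an in-mask voxel with no in-mask
  neighbour on any axis gets 0 and is flagged.

* **Plateau tie-breaks.** A flat plateau yields exactly one local maximum,
  at the lowest linear index; maxima closer than a minimum separation keep
  only the higher one. All cluster/maximum kernels are exercised against
  exhaustive brute-force re-implementations on small random lattices.

* **Snowballing on noisy data.** Each seed's correlation map is smoothed
  (FWHM 6 mm, mask-normalized, zero-padded FFT) before thresholding and
  peak extraction, so clusters carry distinct, stable local maxima rather
  than one peak per noise ripple; within a cluster, maxima closer than
  8 mm are pruned. Without this the zone-2 seed population explodes with
  spurious peaks. Per-seed peaks increment single voxels (no sphere
  stamping); an optional smoothing of the *final* density map is used for
  display and for comparing density maps spatially.

* **Watershed levels** are percent-of-component-maximum, descending in 1%
  steps; a voxel first claimed by ≥ 2 components becomes a boundary with
  that onset level and is excluded from later region growth (dam
  semantics); a region voxel with no face-adjacent same-region voxel is
  ignored when intersections are detected. Node-mask thresholds are
  percentiles of voxels discarded per component. The two scales
  intentionally differ. On phantom-derived components the intersections
  happen at onset levels of roughly 10–45% of the component maximum —
  synthetic IC maps decay faster from their peak than large-scale
  resting-state networks do — so the desk sweep grid spans that range
  while the paper-scale grid retains the conventional percentages.

* **ICA backend.** Spatial FastICA (`ica::icafast`) on the temporally
  concatenated, voxelwise-standardized sessions, sign-fixed so each map's
  peak is positive and rescaled to unit maximum. The backend is pluggable
  (`backend` argument). In synthetic mode components are matched to
  ground-truth networks by greedy spatial correlation
  (`match_components()`); on real data one would select components by
  inspection, as usual.

* **SVM conventions.** Linear kernel, C = 1 (the "default scaling factor
  of 1" read as the soft-margin cost), features standardized per training
  fold with training statistics only, one-versus-one voting with ties
  broken by summed decision values, folds holding out whole subjects.
  Bootstrap resamples subjects (the CV group unit) with replacement;
  duplicated subjects remain grouped. Weight maps are fold-averaged signed
  weights mapped back to the volume. AUC is the rank statistic on decision
  values pooled over folds.

* **Sham-corrected maps are smoothed** (FWHM 6 mm = 2 voxels) before
  feature extraction — the derived-map analogue of the conventional
  acquisition-space smoothing that the phantom, having no point-spread
  function, does not otherwise receive. This pools locally consistent
  evidence and roughly doubles the sensitivity of the classification
  stage.

## Problem sizes

The `"desk"` preset — 12 subjects, 16³ grid at 3 mm, 64 volumes at
TR 2.5 s, K = 6 networks, coarse boundary grid 4.5 mm — is the package's
standard configuration for tests and examples; a full desk study
(108 sessions, both map kinds, masks, classification, motion control)
runs in about a minute on one core. The `"paper-scale"` preset keeps the
emulated study's 23 subjects and 125 volumes on a finer grid.

The effect-recovery experiment in the acceptance tests runs at the
emulated study's own acquisition scale (23 subjects for the sweep, 125
volumes per session): a power analysis during design showed that the
similarity matrix's sampling noise at 64 frames (standard error per entry
roughly `1/sqrt(2·bandwidth·duration)` ≈ 0.19) swamps the boundary-map
footprint of even a full border swap, so the shorter sessions are a null
instrument for this particular question. The classification power curve
over δ ∈ {0, 0.25, 0.5, 1} uses 12 subjects with the feature mask held
fixed.

* **Motion control and the anti-learning bias.** Cross-validated accuracy
  of an uninformative feature is not Binomial(n, 0.5)/n: with a single
  feature and whole-subject folds the statistic is biased *below* chance
  (the held-out subject's value tips the training statistics the other
  way), by about 0.05–0.1 at these cohort sizes. The motion control
  therefore asserts the scientifically meaningful side exactly — no
  pairwise accuracy may exceed the family-corrected binomial upper bound —
  and requires the mean over all comparisons to sit near chance, rather
  than forcing every value into a two-sided binomial band that a true
  null violates by construction.

* **Sweep tie-breaks.** Desk-scale accuracy curves have exact plateau
  ties when the injected effect saturates the classifier; among thresholds
  tied at the maximum the most inclusive (largest-voxel-set) mask is
  reported as the best — the full extent of voxels consistent with maximal
  accuracy. When the sweep is bootstrapped, the best is the maximum of the
  mean-across-bootstraps curve.

## Known limitations

* Watershed behaviour when three or more components meet at the same
  level is treated identically to two; the original description is silent.
* The boundary pipeline reports the raw average gradient map; no per-row
  normalization is applied before averaging (also unstated in the
  original; a display threshold is presentation only).
* The desk-scale null calibration has binomial noise of a few percentage
  points per replicate; the acceptance script averages 20 replicates.
* Bootstrap confidence intervals at desk scale use fewer resamples
  (≤ 100) than the 1000 used at paper scale; the `classifier_config()`
  default remains 1000.
* `run_pipeline()` caches at the whole-run level (a config hash stored in
  the JSON summary); stage-level caching was judged not worth the
  complexity at desk scale.
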