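---
title: "Measuring and modelling the axial precision of two-photon photostimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling the axial precision of two-photon photostimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppsftools)
library(dplyr)
```

## The measurement

Two-photon optogenetics activates single opsin-expressing neurons with a
focused, spiral-scanned laser spot while calcium imaging reads out the
response. The *physiological point spread function* (PPSF) quantifies the
axial targeting precision: the post-stimulation ΔF/F response of a neuron
as a function of the z offset between the stimulation focus and the cell,
summarized by its full width at half maximum (FWHM). This package
implements the complete measurement pipeline — from raw movie, ROI masks
and a voltage-style synchronization trace to per-neuron and group response
curves — together with an analytical model of what sets the PPSF, and a
synthetic-data generator so every stage is testable with known ground
truth.

The emulated experimental design: the stimulation focus is stepped through
nine axial offsets, −60 to +60 µm in 15 µm steps, with three 250 ms spiral
stimulations per offset repeated every 10 s, all repeats at one offset
before moving to the next. Imaging runs at 30 Hz over a 512×512 px field
(~1.25 µm/px). Sweeps run in a "standard" or "reverse" direction,
alternated across neurons to control for opsin desensitization. The
package maps "standard" to the ascending sweep (−60 → +60 µm); because
conventions differ between descriptions of such experiments, the direction
is always an explicit argument and flipping reverse curves onto the
standard orientation is an explicit, tested step (`flip_reverse()`).
Whether +z means "deeper than the imaging plane" is likewise a declared
convention, not something the data can resolve.

## Response extraction

For each trial, the raw fluorescence trace is the mean over the neuron's
ROI pixels. ΔF/F = (F − F0)/F0 with F0 the mean F over the 1.5 s before
stimulation onset; the trial response is the mean ΔF/F from 0 to 1.5 s
after stimulation end. Stimulation-period frames carry the
photostimulation artifact (there is no artifact-reduction strategy) and
belong to neither window — trial windows exclude them by construction.
Trial onsets come from counting frame-clock rising edges up to each
stimulation-gate edge; a frame overlapping the gate at all counts as an
artifact frame. ΔF/F is exactly invariant to multiplying raw F by a
positive constant, which the suite checks; the 5-frame rolling average is
provided for time-series display only and never enters trial statistics.

Three post-processing rules, each tested at its boundary:

* **Inclusion** — a neuron whose per-z mean response never reaches
  0.35 ΔF/F at any offset is excluded as a failed stimulation. The
  threshold applies to the per-z trial mean (the natural reading of "a
  mean of ≥ 0.35"), and a curve peaking at exactly 0.35 is included.
* **Peak alignment** — because the soma's true axial position is uncertain
  by about one z step, each curve's maximum-response offset is relabelled
  z = 0 and the applied shift recorded. Ties break toward the
  smaller-magnitude shift; an exact magnitude tie takes the negative-z
  peak (a declared rule — the data cannot distinguish). Shifts beyond
  15 µm warn rather than error: they indicate something other than
  soma-position uncertainty.
* **Group combination** — per-neuron curves are normalized to their own
  maximum, then averaged pointwise with a normal-approximation 95% CI
  (mean ± 1.96 SE). Strictly, curves relabelled by different shifts no
  longer share a z grid; `combine_group(join = "strict")` rejects them,
  and `join = "union"` averages over the union grid with per-z counts,
  which is what combine-after-relabel requires. The group FWHM is
  computed on the mean normalized curve, not as a mean of per-neuron
  FWHMs.

The group FWHM statistic is the **width at half prominence**: the peak's
prominence is its height above the higher of the two flanking minima
(curve boundaries count as bases), the evaluation height is
peak − prominence/2, and the crossings are linearly interpolated between
samples. On a densely and completely sampled Gaussian this returns the
true FWHM to 0.1%; on the 9-point experimental grid the interpolation
error is below 1 µm for curve widths in the 40 µm range. Flat and
monotone curves return `NA` rather than a number. Conditions are compared
with per-z Welch t-tests, deliberately without multiple-testing correction
across the nine offsets (mirroring how such comparisons are usually
reported); the output carries `p_adjusted = "none"` so downstream users
can correct if they wish.

## OPSF estimation

The optical PSF is estimated from z-stacks of sub-diffraction (0.2 µm)
beads at 0.1 µm lateral and 1 µm axial sampling. Beads are detected as
thresholded 3D local maxima, non-maximum-suppressed and refined by local
center of mass; stacks can be registered slice-wise (FFT cross-correlation
with parabolic sub-pixel peak interpolation, bilinear resampling) to
remove apparent tilt from lateral drift. A 1D Gaussian
`offset + A·exp(−(x−µ)²/2σ²)` is fitted to each bead's axial and lateral
profiles by bounded Levenberg–Marquardt least squares, initialized from
moments. Fits with R² < 0.9 are flagged unusable — an automated,
configurable stand-in for eyeballing fit quality. The σ lower bound is
0.2× the sample spacing: a bound proportional to the profile window would
wrongly exclude narrow profiles (a 3.5 µm σ in a ±20 µm window). The
summary FWHM per axis is the mean of per-bead fitted FWHMs with a normal
95% CI; the mean-curve-then-fit alternative gives the same answer on
synthetic data but is not what `summarize_opsf()` reports.

## The convolution model

A spherical soma of diameter d has constant membrane area per unit z
across its diameter (the area of a spherical zone is independent of where
the slab sits), so its axial excitation profile is a top-hat — the package
verifies this numerically from a voxelized shell. With a Gaussian axial
OPSF of standard deviation σ = FWHM/2.3548, the model PPSF is their
convolution, with closed form Φ((z+d/2)/σ) − Φ((z−d/2)/σ). The package
computes it two independent ways:

* `convolve_normalize()` — discrete FFT convolution on a regular grid
  (default 0.1 µm over ±80 µm), peak-normalized. The deterministic
  Gaussian density replaces any stochastic construction of the Gaussian
  from random samples, which converges to the density anyway. A sample
  landing exactly on a top-hat edge takes the jump midpoint value 0.5 —
  the standard discretization of a discontinuity — which keeps the
  discrete result unbiased when edges coincide with grid points.
  Smoothing (a centred moving average) is off by default for FWHM
  reporting because its effect depends on grid spacing; it exists for
  reproducing smoothed display curves.
* `erf_oracle_fwhm()` — the closed form, solved for its half-maximum by
  bisection to 1e-6 µm.

The two agree to better than 0.001 µm in FWHM across d = 0–50 µm at
0.05 µm spacing. Limits behave as they must: d → 0 returns the OPSF FWHM;
a near-delta OPSF returns d; the FWHM is non-decreasing in both d and
OPSF width. For the two OPSF conditions studied throughout the package
(axial FWHM 8.3 and 18.6 µm), the model PPSFs converge to within 2 µm of
each other at d = 26 µm and stay converged — beyond roughly cell-sized
diameters, precision is set by the cell, not the optics.

## The synthetic-data generator

The generator defines the study conditions under which everything is
tested; its defaults are the experimental constants above (9 × 15 µm z
grid, 3 trials, 250 ms stimulation, 10 s repeats, 30 Hz, ~1.25 µm/px,
15 µm somata — layer-2 pyramidal scale). Choices the experiments do not
pin down are declared here:

* **Dose model.** The 10 µm spiral tiles the soma laterally, so the dose
  at offset z reduces to the 1D axial convolution of the cell profile
  with the axial OPSF (midpoint quadrature on a symmetric grid, exact
  symmetry preserved). The lateral OPSF enters only bead rendering.
* **Dose → response.** A Hill law
  A = A_max qⁿ / (qⁿ + q_½ⁿ): zero at zero dose, monotone, saturating.
  Defaults (A_max = 8 ΔF/F, q_½ = 2 in relative dose units, n = 1) put
  the working range on the quasi-linear foot of the curve with ~1.5–2.6
  ΔF/F peak responses — emulating experiments that deliberately choose
  sub-saturating stimulation power so the response curve can be sampled.
  Saturation is available by lowering `half_dose` or raising `n`.
* **Transient kernel.** (1 − e^(−t/τ_rise)) e^(−t/τ_decay), peak-scaled,
  τ_rise = 0.2 s, τ_decay = 1.5 s — GCaMP6s-like.
* **Noise.** Shot noise as Gaussian with sd ∝ √signal plus additive read
  noise; every stochastic function takes an explicit seed and restores
  RNG state (`withr::with_seed`), so identical seeds give bit-identical
  outputs.
* **Artifact.** An additive constant in target pixels during stimulation
  frames only.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: out-of-focus excitation beyond the Gaussian
focus, perisomatic (Kv2.1-style) opsin extending onto proximal dendrites,
scattering and aberrations at depth, neuropil contamination, motion, and
spiking nonlinearity between photocurrent and calcium. The model layer
likewise predicts geometry-limited precision, not these biological
contributions; on real recordings the measured group FWHM exceeds the
geometric prediction, and that gap is informative, not an error.

One deliberate simulation compromise: in the full movie path, a trial's
GCaMP transient decays into the next trial's baseline window. At the 10 s
inter-trial default the carry-over is ~0.5% of the peak; the noiseless
round-trip test therefore checks the measured responses against the full
forward model (tails included) to 1e-8, while direction-invariance of
group curves holds to the size of the carry-over (~1%). The fast path
(`simulate_response_curves()`), which draws trial responses directly, is
exactly order-invariant.

## Problem sizes and numerical choices

The test-suite and acceptance-script simulations are scaled to what the
checks need, stated here as the package's own choices: bead stacks of
61–141 slices at 64–96 px laterally (enough for ±3σ support of both OPSF
conditions), 20 noisy stacks per condition for recovery statistics
(median relative FWHM error ~0.1–0.2%, threshold 5%), movie cohorts of
3 neurons per direction at 48×48 px with the full 27-trial protocol, 16
fast-path neurons per condition for the stochastic null-result check, and
1000 replicates for the Welch type-I rate (held within [0.035, 0.065]).
Model-grid defaults (0.1 µm spacing, ±80 µm) keep the grid covering ±3σ
of the widest OPSF plus the largest cell radius; the FWHM bisection
tolerance is 1e-6 µm. Degenerate inputs return failure values, not
numbers: flat or monotone curves give `NA` FWHM, all-constant stacks give
zero detections, non-converged fits are distinct from converged-but-poor
fits.

## A small end-to-end run

```{r example, eval = FALSE}
sim <- simulate_experiment(
  cells    = list(cell_spec(center = c(20, 20, 0), diameter = 15)),
  protocol = stim_protocol(inter_trial = 10),
  acq      = acquisition_spec(frame_shape = c(32, 32)),
  opsf     = opsf_model(axial_fwhm = 18.6, lateral_fwhm = 1.8),
  seed     = 42)

trials <- mutate(detect_trial_onsets(sim$sync), z_um = sim$truth$z_um)
rc <- build_response_curve(sim$movie, sim$rois[[1]], trials,
                           frame_rate = 30, neuron_id = "cell_1")
autoplot(rc)

g <- combine_group(list(align_to_max(rc)), join = "union")
fwhm_half_prominence(g$z_um, g$mean_response)  # ~21.9 um
erf_oracle_fwhm(18.6, 15)                      # 21.55 um, closed form
```

`run_pipeline()` wraps the same stages behind a YAML config and writes
per-neuron curves, the group curve, a stats JSON (group FWHM, inclusion
counts, threshold) and a log of per-neuron inclusion decisions;
`make_fixtures()` writes deterministic on-disk datasets for the four
standard scenarios (`beads_small`, `beads_large`, `cohort_null`,
`cohort_shifted_peak`).

## Known limitations

The pipeline takes ROI masks as input; drawing ROIs is out of scope.
Cross-acquisition motion registration is integer/sub-pixel translation
only — adequate for synthetic data and declared replaceable for real
movies with non-rigid motion. The model is 1D and axial; lateral PPSF,
holographic multi-target stimulation, wave-optical effects and opsin
kinetics are out of scope. OPSF estimation at non-zero SLM offsets is not
attempted.
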