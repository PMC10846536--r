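# ppsftools

Tools for quantifying the **axial precision of two-photon optogenetic
photostimulation** from calcium-imaging data.

In all-optical neuroscience experiments, a focused (often spiral-scanned)
two-photon beam activates an opsin-expressing neuron while calcium imaging
reads out its response. The practical unit of targeting precision is the
**physiological point spread function (PPSF)**: the neuron's response
amplitude as a function of the axial displacement `z` between the
stimulation focus and the cell, summarized by its full width at half
maximum (FWHM). The PPSF is always broader than the **optical point spread
function (OPSF)** of the beam itself, because the cell has finite size: to
first order the PPSF is the convolution of the axial OPSF with the cell's
axial profile,

```
PPSF(z) = (cell ⊛ OPSF)(z),   cell(z) = 1{|z| ≤ d/2},   OPSF(z) ∝ exp(−z² / 2σ²)
```

with `σ = FWHM_OPSF / (2√(2 ln 2))` and `d` the soma diameter (a sphere's
membrane area per unit z is constant across its diameter, so the cell term
is a top-hat). The closed form of that convolution is
`Φ((z + d/2)/σ) − Φ((z − d/2)/σ)`, which the package also implements as an
independent oracle for its discrete pipeline. A key consequence: once
`d` exceeds the OPSF axial FWHM, the PPSF FWHM depends almost entirely on
the cell diameter — improving optics beyond that point buys no precision.

The package provides four layers, all tibble-first and pipe-friendly:

- **`synth`** — synthetic data with known ground truth: fluorescent-bead
  z-stacks rendered from a parametric Gaussian OPSF, full photostimulation
  movies (T×Y×X) with GCaMP6s-like transients, a Hill dose–response law, a
  frame-clock/stimulation-gate synchronization record, and a fast path that
  skips movie rendering (`generate_bead_stack()`, `simulate_experiment()`,
  `simulate_response_curves()`).
- **`opsf`** — OPSF estimation from bead stacks: bead detection,
  translation registration, profile extraction, bounded Gaussian least
  squares with an R² usability flag, and per-axis FWHM summaries with 95%
  CIs (`fit_bead_stack()`, `summarize_opsf()`).
- **`ppsf`** — the movie → response-curve pipeline: trial location from
  sync edges, ΔF/F against a 1.5 s pre-stimulation baseline, mean response
  0–1.5 s post-stimulation (stimulation-artifact frames excluded), the
  0.35 ΔF/F inclusion filter, peak alignment, reverse-sweep flipping, group
  curves with 95% CIs, FWHM at half prominence, and per-z Welch tests
  (`build_response_curve()`, `combine_group()`, `fwhm_half_prominence()`).
- **`model`** — the convolution model and its analysis:
  `ppsf_vs_diameter()`, `convergence_diameter()`, `erf_oracle_fwhm()`.

Results have `tidy()` / `glance()` methods and `autoplot()` ggplots;
`run_pipeline()` executes the whole analysis from a YAML config and writes
CSV/JSON outputs plus a run log.

## Worked example

Model PPSF FWHM against cell diameter for the two OPSF conditions (8.3 and
18.6 µm axial FWHM):

```r
library(ppsftools)
ppsf_vs_diameter(c(18.6, 8.3), diameters = c(0, 10, 20, 30, 40))
#>    opsf_fwhm_um diameter_um ppsf_fwhm_um equality_um
#> 1          18.6           0    18.600000           0
#> 2          18.6          10    19.875927          10
#> 3          18.6          20    24.005647          20
#> 4          18.6          30    31.138529          30
#> 5          18.6          40    40.224535          40
#> 6           8.3           0     8.300233           0
#> 7           8.3          10    11.365834          10
#> 8           8.3          20    20.040250          20
#> 9           8.3          30    30.000184          30
#> 10          8.3          40    40.000000          40
convergence_diameter(18.6, 8.3, tolerance = 2)
#> [1] 26
```

At zero diameter each curve returns its own OPSF FWHM; by `d ≈ 26 µm` the
two conditions are within 2 µm of each other and converge onto the line of
equality (`ppsf_fwhm_um ≈ diameter_um`) — cell size, not optics, sets the
precision.

Simulate a photostimulation experiment (9 z offsets from −60 to +60 µm,
3 trials each, 250 ms stimulation, 30 Hz imaging) and measure the curve:

```r
library(dplyr)
sim <- simulate_experiment(
  cells    = list(cell_spec(center = c(20, 20, 0), diameter = 15)),
  protocol = stim_protocol(inter_trial = 10),
  acq      = acquisition_spec(frame_shape = c(32, 32)),
  opsf     = opsf_model(axial_fwhm = 18.6, lateral_fwhm = 1.8),
  seed     = 42)

trials <- mutate(detect_trial_onsets(sim$sync), z_um = sim$truth$z_um)
rc <- build_response_curve(sim$movie, sim$rois[[1]], trials,
                           frame_rate = 30, neuron_id = "cell_1")
rc
#> <response_curve> neuron cell_1, 9 z offsets x 3 trials, standard direction, shift 0 um
#> # A tibble: 9 × 6
#>   neuron_id  z_um  mean_dff n_trials direction applied_shift_um
#>   <chr>     <dbl>     <dbl>    <int> <chr>                <dbl>
#> 1 cell_1      -60  4.57e-11        3 standard                 0
#> 2 cell_1      -45  3.14e- 6        3 standard                 0
#> 3 cell_1      -30  6.68e- 3        3 standard                 0
#> 4 cell_1      -15  4.74e- 1        3 standard                 0
#> 5 cell_1        0  1.50e+ 0        3 standard                 0
#> 6 cell_1       15  4.72e- 1        3 standard                 0
#> 7 cell_1       30  6.20e- 3        3 standard                 0
#> 8 cell_1       45 -3.62e- 6        3 standard                 0
#> 9 cell_1       60 -3.13e- 9        3 standard                 0

inclusion_filter(rc)        # peak 1.50 dF/F >= 0.35: neuron is responsive
#> [1] TRUE
g <- combine_group(list(align_to_max(rc)), join = "union")
fwhm_half_prominence(g$z_um, g$mean_response)
#> [1] 21.90574
erf_oracle_fwhm(18.6, 15)   # closed-form prediction for this geometry
#> [1] 21.55197
```

The measured group FWHM (21.9 µm) sits within a fraction of the 15 µm z
sampling step of the closed-form prediction (21.6 µm); the residual comes
from the saturating dose–response law and the coarse z grid.

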