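---
title: "Methods: models, calibration, and numerical choices in tadcal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, calibration, and numerical choices in tadcal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadcal)
```

`tadcal` quantifies widefield GCaMP6s calcium imaging and locomotor
tracking of tadpole epilepsy models: ΔF/F₀ conversion, pooled-threshold
event detection, low-frequency spectral power, interhemispheric
synchrony, and swim/darting metrics, plus a synthetic generator that
emulates a control cohort, a CRISPant (seizure-model) cohort, and a
drug-treated cohort with known ground truth. This vignette records the
models, the tunable parameters and their defaults, the calibration of
the generator, and the numerical decisions a maintainer would want
explained.

## Imaging model

A recording is a `T × H × W` stack at `fs = 2` Hz (30 min, 3600
frames in the emulated experiment). The baseline image `F₀` is the
per-pixel temporal **median** over the full recording — robust to sparse
transients, and for an even frame count the mean of the two central
order statistics. ΔF/F₀ is reported in percent. Pixels with `F₀ ≤ 0`
cannot be normalised; they are flagged invalid and excluded from every
downstream average (never silently set to zero), so synthetic or dark
pixels cannot poison traces with NaNs. Coordinates are (row, column)
with row 1, column 1 at the top-left; masks are pixel-centre membership.

ΔF/F₀ is scale-free, so raw fluorescence units are arbitrary; the
package stores movies in the unit range, which is also what the 32-bit
TIFF writer preserves (values survive a round trip to ~2⁻³²).

## Event detection

Whole-brain traces are high-pass filtered at `cutoff_hz = 0.005` Hz to
remove slow baseline drift. The filter is a 2nd-order Butterworth
applied forward and backward: zero phase, so event peak times are not
shifted, at the cost of squaring the magnitude response (the effective
attenuation at the cutoff is −6 dB). At a relative cutoff of 0.005/1 Hz
the startup transient of a naively initialised recursion is enormous, so
each pass is initialised at its steady state for a step equal to the
first sample and the trace is extended by odd reflection — a constant
trace then maps to numerically zero, and edge artefacts are below 1% of
a passband signal.

The detection threshold is **3 × the population SD of all samples of
all filtered control traces pooled together**, computed once per study
and applied uniformly to every animal and group; no per-trace
adaptation. The SD uses the population (n) denominator — at 43,200
pooled samples the n vs n−1 distinction is negligible, but it is fixed
for exactness of the forced-example tests.

Peaks are local maxima of the filtered trace (plateaus peak at their
first sample) screened in three steps: full width at **half prominence**
at least `min_width_s = 5` s, then minimum peak separation
`min_distance_s = 5` s keeping the higher peak (ties to the earlier),
then the fixed threshold. Prominence uses the standard topographic
convention (down to the higher of the two minima separating the peak
from its nearest higher neighbours or the trace ends), and widths are
linearly interpolated at the reference level. Event amplitude is the
filtered-trace value at the peak sample — the same signal the threshold
is applied to. The width convention and the filtered-amplitude choice
are this package's documented readings of the underlying protocol, which
specifies only "minimum width and distance constraints" and thresholding
on the filtered trace.

A note on timing accuracy: the detector has no systematic shift (the
filter is zero-phase), but the argmax of a smooth peak jitters by
roughly `noise SD / (amplitude × peak curvature)`. One-sample timing
accuracy therefore holds for events that are large relative to the
noise; at the CRISPant preset's noise level a measurable fraction of
detected peaks lands 2 samples off, which is why the timing assertion in
the test-suite uses modest noise while sensitivity (≥ 95% recovery) is
asserted at preset noise.

## Spectral analysis

Per-ROI (or whole-brain) raw ΔF/F₀ traces are linearly detrended,
tapered with a 10% split-cosine bell, Fourier transformed, and converted
to a single-sided power density in (ΔF/F₀)²/Hz. The normalisation is
Parseval-consistent — the trapezoidal integral of the density over
(0, Nyquist] equals the variance of the (detrended, taper-compensated)
trace — so integrated band power is directly interpretable as signal
variance in the band. Densities are linearly interpolated onto a common
grid spanning 0.01–1 Hz at 0.0001 Hz spacing; all spectra in a study
share the identical grid vector, enabling pointwise averaging (per-animal
mean across ROIs, group mean ± t-based 95% CI across animals) and the
trapezoidal band integral that yields the per-animal low-frequency power
scalar.

Three numerical choices deserve explanation:

* **Taper.** The classic 10% split-cosine bell (the default taper of
  R's own periodogram) suppresses spectral leakage from the record's
  endpoints. This matters here: a minutes-long calcium event truncated
  by the end of a 30-min recording otherwise leaks broadband power into
  0.01–1 Hz through the DFT's circular discontinuity, inflating band
  power by tens of percent for plateau-rich cohorts. The taper is
  power-normalised (divide by the mean squared taper), which keeps
  broadband Parseval exact and biases a pure line component by under
  3%. A rectangular window remains available (`taper = 0`).
* **Grid spacing.** Interpolation onto a grid whose nodes do not
  include the native Fourier frequencies does not conserve the area of
  line-like spectra; at 0.0001 Hz spacing (well below the native
  1/1800 Hz) the trapezoid-over-interpolant error is below 1% even for
  a pure sinusoid, and negligible for smooth spectra.
* **Detrending and input choice.** The PSD is computed on raw,
  detrended traces, not the 0.005 Hz-filtered ones: the grid starts at
  0.01 Hz, so drift below 0.005 Hz is excluded anyway (the synthetic
  drift period, 900 s, additionally divides the 1800 s record, so the
  drift line falls exactly on a native bin and cannot leak). Both the
  filter question and the window are configurable.

## Synchrony

Interhemispheric synchrony is the Pearson correlation between raw
ΔF/F₀ traces of fixed-area circular ROIs at the geometric centroids of
the four region masks (left/right forebrain and midbrain). The ROI is
grown from the nominal radius `sqrt(area/π)` until it holds at least
`area_px = 500` pixel centres and trimmed to exactly 500 by distance
rank with a row-major tie-break — the fixed pixel count is treated as
exact. Centroid circles may extend beyond a concave region (no clipping
language exists in the underlying protocol); `clip_to_region = TRUE` is
available but off by default. Zero-variance traces yield flagged `NA`
correlations, never silent zeros.

## Locomotion

Trajectories are 50 fps centroid tracks in mm. The velocity series is
the frame-to-frame Euclidean displacement times the frame rate, smoothed
by a 5-frame centred moving average (edges truncated) to suppress
single-frame centroid jitter; metrics are the mean velocity, the total
path length, and darting — the percentage of frames whose velocity
exceeds a shared threshold, default 20 mm/s. The commercial tracker this
replaces does not publish its burst detector, so the threshold is an
explicit configuration value; comparisons are only meaningful when all
cohorts share one value.

## The synthetic generator and its calibration

Each planted event contributes `A · k(t − t₀)` with unit-peak kernel

```
k(t) ∝ [exp(−t/τ_d) − exp(−t/τ_r)]  +  w · exp(−(t − t_p)² / 2σ_p²)
```

a fast difference-of-exponentials transient (rise τ_r = 2 s; decay
τ_d = 12 s control, 10 s CRISPant cohorts) plus a Gaussian plateau of
scale σ_p (30 s control, 45 s CRISPant/treated) centred on the transient
peak. The plateau reproduces the prolonged, minutes-long envelope of
seizure-like events — at the CRISPant preset the raw ΔF/F₀ envelope of
a typical event stays above the control-derived threshold level for
over two minutes — while the transient carries the fast structure. Event times are Poisson in number and
uniform over the recording subject to a 60 s hard-core separation;
the placement is **resampled** until feasible rather than thinned by
deletion, because deletion would bias the mean count ~10% below the
configured rate. Amplitudes are normal, truncated at zero, with SD fixed
at 25% of the mean (the published data report only cohort means ± SEM of
detected amplitudes; a fixed coefficient of variation keeps cohort means
identifiable). Traces add a slow sinusoidal drift (amplitude 0.5%,
period 900 s, random phase) and white noise (SD 0.05 / 0.15 / 0.10
ΔF/F₀% for control / CRISPant / treated — small enough that the 3σ +
5 s-width detector has essentially zero false positives, large enough to
exercise the pipeline).

The presets must reproduce the *detected* statistics of the cohorts
they emulate: mean event count, mean detected amplitude, and integrated
band power (control 1.67 / 3.94% / 0.11; CRISPant 3.46 / 8.20% / 0.58;
losartan-treated 2.30 / 7.32% / 0.230; synchrony ρ 0.79/0.72 control,
0.96/0.88 CRISPant for MB/FB). Count and amplitude are direct: the
planted rate is the target rate (detection is ~99% at these amplitudes),
and the planted amplitude is the target divided by the kernel's measured
high-pass attenuation (long events lose 30–65% of their peak to the
filter). Band power constrains the kernel *shape*: with rate and
amplitude fixed, the expected event contribution to 0.01–1 Hz power is
`rate · E[A²] · E_band / T`, where `E_band` is the kernel's in-band
energy averaged over event positions (including boundary truncation).
The plateau weight `w` is therefore solved by root-finding so that
`E_band / attenuation²` matches the power budget left after noise. This
calibration is a deterministic forward-model solve — no random numbers,
no fitting to pipeline output — performed identically at every preset
construction (about a second, cached). `analysis/01_calibrate_presets.R`
tabulates the result; the solved plateau weights rise from ~0.27
(control) through ~1.8 (CRISPant) to ~3.0 (treated) because the
published band power per event falls relative to the published
amplitude.

Homotopic synchrony is realised two ways. The **mixing model**
(`mix_correlated_pair`) standardises a shared cohort trace `z` and forms
`√ρ·z + √(1−ρ)·n` for each side with independent noise; its expected
Pearson correlation is exactly ρ, which is why cohort synchrony is
measured through this path. The **movie renderer** instead shares
planted events bilaterally with probability `p_shared` (0.5 control, 0.9
CRISPant), drawing pair-level trains whose per-side marginal rate equals
the preset rate — more realistic spatially, but with an emergent rather
than exact correlation. Movies render regions multiplicatively over a
static smooth baseline (`F = F₀·(1 + trace/100)` inside a region) with
additive pixel noise; the default geometry is a 96 × 96 elliptical brain
with four elliptical hemispheric regions (each ≥ 500 px), scaled
fractionally to any frame size.

Trajectories follow a random-heading walk (Gaussian heading increments,
90°/s SD) at the cohort cruising speed with Poisson darting bursts, and
reflect at the wall of a 7.8 mm-radius arena (a 24-well plate well).
The treated preset cruises at 0.11 mm/s with darting suppressed — the
published post-treatment mean velocity — while CRISPant kinematics
(0.24 mm/s cruise, 1.2 darts/min at 35 mm/s) put the cohort mean near
the published 0.41 mm/s; the control cruising speed (0.14 mm/s) is a
nominal choice, as no control velocity is printed.

Recording geometry defaults to the study's: 30 min at 2 Hz, cohorts of
12 (control), 13 (CRISPant), and 10 (treated). Presets always calibrate
kinetics at the 30-min recording; shorter requested durations keep the
calibrated kernel and scale the rate proportionally (constant temporal
density), since the published statistics describe only the 30-min
regime. Cohort seeds derive from one master seed by fixed offsets
(`master·10⁴ + offset + animal`), keeping cohorts' streams disjoint and
reproducible.

## What the generator does and does not emulate

The generator reproduces the cohorts' detected-event statistics, band
power, homotopic correlation means, and post-treatment velocity, with
Poisson count variability across animals. It does **not** model: optics
(no point-spread function, photobleaching, or motion), hemodynamic or
scatter contamination, between-animal variability in amplitude scale,
kinetics, or synchrony (ρ is identical across a cohort's animals, so
mixing-model correlations have far less spread than real cohorts — group
tests on synthetic synchrony are anticonservative relative to the
published p-values), or any within-recording nonstationarity. Passing
tests therefore demonstrate that the *pipeline* recovers known structure
at realistic signal levels, not that the generator is a complete model
of tadpole brain activity.

## Statistics

Group summaries are mean ± SEM (SD with n−1). The comparison policy
mirrors the study: a Shapiro–Wilk gate at α = 0.05 selects Welch's
unequal-variance t (or the paired t) when both groups pass, otherwise
the Mann–Whitney U (or Wilcoxon signed-rank for paired designs); both
branches are always computed and stored, and all tests are two-sided.
Exact p-values are used for small untied samples (U: smaller group ≤ 8;
signed-rank: ≤ 12 nonzero pairs), otherwise normal approximations with
tie and continuity corrections; the implementations wrap R's `stats`
tests behind the module interface and are cross-checked in the test
suite against full enumeration oracles. No multiple-testing correction
is applied (none is used in the emulated analysis); this is a documented
limitation.

## Problem sizes used by the tests and scripts

The test-suite and acceptance script run the full study geometry in
trace space (35 animals × 3600 samples, plus 50 mixing pairs and 11
one-hour 50 fps trajectories — a few seconds each) and scale movie-space
checks to 32–48 px frames and 2.5–15 min durations, which exercise every
imaging code path at a fraction of the memory of a full 96 × 96 × 3600
movie. Monte-Carlo property tests use 10⁴ replicates where a rate is
asserted (Poisson calibration, type-I error) and 200–1000 replicates for
oracle-agreement sweeps.
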