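---
title: "Measuring conduction and repolarization from cardiac optical maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring conduction and repolarization from cardiac optical maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# What this package measures

Panoramic optical mapping images cardiac electrical activity with a
voltage-sensitive dye and a high-speed camera: every pixel's fluorescence
trace is a surrogate transmembrane potential (the raw dye signal
*decreases* on depolarization). From a paced recording `cardiomap`
extracts the standard electrophysiological quantities:

- **Activation time** per pixel: the time of the steepest phase-0
  upstroke, i.e. the maximum of the first temporal derivative inside a
  beat window.
- **APD80**: action potential duration from activation to 80%
  repolarization — the first post-peak time the trace recovers to
  baseline + 20% of the beat amplitude.
- **Conduction velocity (CV)** by the single-vector two-point method:
  Euclidean distance between two points along the apparent propagation
  axis divided by their activation-time difference.
- **Diastolic interval** DI = CL − APD80 and the **APD restitution
  curve** (APD80 against preceding DI) with its maximum local slope;
  slopes approaching 1 are classically pro-arrhythmic.
- **Group statistics** in the conventional layout: per-cycle-length
  means ± SD, Kruskal–Wallis omnibus test, Dunn's post hoc pairwise
  comparisons, and a linear-model trend across cycle lengths, plus the
  Teichholz M-mode ejection fraction for the echocardiographic arm.

Because real dye recordings of this kind are rarely shared, the package
pairs the measurement chain with a synthetic movie generator, so every
stage can be validated by parameter recovery: generate a movie whose
ground truth is known, push it through the pipeline, and compare.

# The synthetic tissue

## Acquisition geometry and pacing

Defaults mirror a typical panoramic rig: a 128 × 128 sensor over a
30 × 30 mm field (0.234375 mm/pixel), 2-ms frames, 2-s recordings, and
constant pacing trains at cycle lengths 400, 300, 250, 200 and 150 ms
delivered by a 3-ms line stimulus at one edge. The first stimulus is
delayed 20 ms so a diastolic baseline is visible.

## Plane-wave generator (analytic oracle)

`plane_wave_movie()` writes down the answer in closed form: a pixel at
distance $x$ from the stimulated edge activates exactly $x/v$ after each
stimulus; the action potential is a raised-cosine upstroke of 2 ms
(maximum slope exactly at the activation time) followed by a linear
repolarization that crosses the 80% level exactly `apd80` ms after
activation, with a short tail back to baseline. Nothing about the
detector is assumed — the waveform is chosen so the quantities being
measured have exact closed-form values.

## Reaction–diffusion simulator

`simulate_tissue()` integrates a two-variable phenomenological
excitable-medium model of the Aliev–Panfilov family,

$$\partial_t u = D \nabla^2 u + \left[-k u (u-a)(u-1) - u v\right]/\tau,$$
$$\partial_t v = \rho\left[\varepsilon_0 + \frac{\mu_1 v}{u + \mu_2}\right]
  \left[-v - k u (u - a - 1)\right]/\tau,$$

with no-flux boundaries and forward-Euler stepping (in compiled code).
This class reproduces what is actually measured here — activation and
repolarization *timing*, restitution, conduction — at desk scale, which
is why it is preferred over ionic models whose extra currents would be
unobservable through a 2-ms camera anyway.

Parameters that matter, with units and defaults:

| parameter | meaning | default | why |
|---|---|---|---|
| `diffusivity` $D$ | mm²/ms; sets CV ($\mathrm{CV}\propto\sqrt D$) | 0.5 (control) | calibrated once so measured control CV ≈ 80–85 cm/s |
| `repol_rate` $\rho$ | recovery-rate multiplier; smaller → longer APD | 1 (control) | calibrated so control APD80 ≈ 80 ms at CL 400 |
| `excitability` $a$ | dimensionless excitation threshold | 0.08 | standard for this model family |
| $\tau$ (`t_scale`) | ms per model time unit | 2.0 | fixes the upstroke to ~2 ms and APD to the physiological decade |
| $k,\varepsilon_0,\mu_1,\mu_2$ | reaction constants | 8, 0.002, 0.2, 0.3 | canonical values for this model family |

The two phenotype presets are stored as an editable configuration
(`phenotype_presets()`): **control** as above, and **hf** (failing
myocardium) with diffusivity × 0.4 and recovery rate × 0.6 — slower
conduction, longer action potentials, steeper restitution. The scalings
were fixed once, before any comparison, so that measured values fall in
the physiological ranges for healthy vs failing rabbit ventricle
(control CV ~80 cm/s and APD80 ~80 ms; failing CV ~50 cm/s and APD80
~125 ms at CL 400). In the four-group analysis workflow the denervated
failing group is modeled as *partial* remodeling (diffusivity ~70% and
recovery ~80% of control) — the package takes no position on mechanism,
it only encodes "between the presets".

A seeded, smooth (±2%) spatial heterogeneity of the excitation
threshold makes different "subjects" differ; subject-level lognormal
jitter of diffusivity (sd 0.10) and recovery rate (sd 0.05) produces
between-animal spread comparable to reported group SDs. All randomness
flows from one explicit seed, and the caller's RNG state is never
touched.

`add_acquisition_noise()` adds per-pixel white noise at a chosen
amplitude SNR plus a slow sinusoidal baseline drift, and the generators
emit dye-like polarity by default so the analysis side must handle
signal inversion.

## What the generator does *not* emulate

No anisotropic fiber architecture, no 3-D geometry or curvature, no
motion artifact (an excitation–contraction uncoupler is assumed
effective), no vendor camera formats, no pacing-capture failures beyond
an explicit sub-threshold stimulus. Passing the recovery suite therefore
shows the *measurement chain* is correct and noise-robust; it does not
certify performance on recordings whose artifacts lie outside this
model.

# Numerical choices

- **Integration step.** Forward Euler needs $\Delta t \lesssim h^2/4D$;
  the simulator uses $\min(0.05, 0.2\,h^2/D)$ ms (≈ 0.022 ms at the
  default pitch and diffusivity), well below the 2-ms frame so the
  upstroke is resolved and ground truth is stable. The recovery-rate
  denominator $u+\mu_2$ is floored at 0.05 — a known safeguard in this
  model family against blow-up when diffusion undershoots $u$ below
  $-\mu_2$.
- **Sub-frame activation refinement.** The discrete-derivative peak is
  refined by parabolic interpolation, clamped to ±1 frame. With a ≤2-ms
  upstroke sampled at 2 ms the refinement has an irreducible
  phase-dependent bias of roughly ±0.2 ms (we evaluated centroid,
  spline and sinc-upsampling estimators; none beat the parabola on this
  waveform class). Two consequences are designed in: spatial smoothing
  before detection averages part of this bias away, and the automatic
  probe spans 80% of a generous ROI so the activation-time difference
  (≥ ~9 ms even at 105 cm/s) dominates the residual timing error. This
  is why CV recovery stays within 5% across 30–105 cm/s.
- **Level crossings.** The 80% repolarization time is linearly
  interpolated between the two bracketing samples; the *first* crossing
  after the peak defines the event. Baseline and amplitude are per-beat
  (pre-stimulus mean and in-window peak), which makes APD robust to
  slow drift.
- **Validity gating.** A pixel contributes only if its beat amplitude
  is ≥ 0.3 of its normalized range and its peak derivative exceeds 5×
  the baseline derivative noise; pixels with amplitude/noise < 3 are
  masked entirely. Invalid pixels are `NA`, never exceptions; a cycle
  length whose ROI is > 50% invalid is flagged low-quality.
- **Normalization.** Per-pixel robust (1st/99th percentile) rescale to
  [0, 1]; flat pixels are flagged, not rescaled; the operation is
  idempotent. Percentiles rather than extremes so a single noise spike
  cannot set the scale.
- **Filtering.** Gaussian σ = 1 px then Savitzky–Golay (window 5,
  order 3), applied only when the median pixel SNR is below 20 — clean
  data are not silently smoothed. `(0, 1)` settings are the bit-exact
  identity.
- **Probe degeneracies.** Activation-time differences below 0.5 ms (a
  quarter frame after refinement) are refused rather than returning an
  unbounded velocity; an incoherent gradient field (circular variance
  > 0.5, e.g. a radial wave) makes the automatic probe refuse and
  advise manual placement.

# Statistical design

- **Kruskal–Wallis** H (tie-corrected) and its chi-square p come from
  the standard implementation; for total n ≤ 8 the p value is instead
  computed *exactly* by enumerating all assignments of the pooled
  observations to groups, because the chi-square approximation is
  unreliable at such sizes. The exact path is validated in the tests
  against an independent brute-force enumeration.
- **Dunn's post hoc** runs only when the omnibus p < 0.05 (overridable,
  and the gating is recorded). Because multiplicity adjustment practice
  varies, both unadjusted and Holm-adjusted p values are reported,
  clearly labeled.
- **Trend across cycle lengths** is a linear model of the measurement
  on the rank of the cycle length (equally spaced ordinal scores) with
  subjects as replicates, two-sided p for the slope. Ranks follow the
  conventional table order from the longest CL to the shortest, so APD
  shortening under faster pacing appears as a *negative* slope.
  Subject-level (not group-mean) observations are used, since that is
  the defensible default when the aggregation level is unspecified.
- **Restitution slope.** "Slope in each part of the curve" is
  formalized as segmentwise chord slopes with the maximum reported —
  transparent and assumption-free. An exponential fit
  $APD = A - B e^{-DI/\tau}$ is offered as well (its maximum derivative
  over the observed DI range is attained at the smallest DI); a
  non-convergent fit falls back to segmentwise with a warning.
- **SD** uses the n−1 denominator; a single-subject group reports a
  missing SD. **APD80** is tabulated at 400–200 ms only by default:
  at very short cycle lengths fusion and alternans make the measurement
  ill-defined (the 150-ms column is available behind an explicit
  override). **Teichholz** volumes are computed in cm
  ($V = 7.0/(2.4+D)\,D^3$), with an explicit unit switch for mm input.

# Problem sizes used in the shipped validation

The test-suite and acceptance computations run the generators at 48–64
px grids at the native pixel pitch (the physics is identical up to
discretization; the upstroke width ~1 mm stays well-resolved), with
4-beat trains per cycle length, 5 subjects per phenotype, SNR 10–20
noise, and 2000-replicate null calibrations. These sizes were chosen as
the smallest at which every measured quantity is stable to well under
its acceptance tolerance.

# Known limitations

- The single-vector CV inherits the judgment embedded in probe
  placement; the automatic probe makes that judgment reproducible but
  is still a two-point method — full vector-field CV mapping is out of
  scope by design.
- Sub-frame timing accuracy is bounded by the 2-ms camera clock as
  discussed above; quantities that depend on *differences* of a few ms
  (e.g. CV above ~1 m/s over short probes) carry the largest relative
  error.
- The simulator is isotropic and two-dimensional; it cannot produce
  breakthrough patterns, scroll waves, or fiber-rotation anisotropy.
- The exact Kruskal–Wallis enumeration is combinatorial and is capped
  at total n = 12.
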