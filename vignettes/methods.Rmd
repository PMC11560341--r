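---
title: "Methods: from nerve stretch to CAP loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from nerve stretch to CAP loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nervestretch)
```

This vignette is the package's own account of its models and the choices
behind them: what is assumed, which knobs matter, what the synthetic data
emulate (and what they do not), and where the design was genuinely open.

## The experimental setting

An excised nerve is held between two sutures in a recording chamber, stepped
through stretch ratios λ = 1.000, 1.025, …, 1.200, and stimulated at each
level (0.33 Hz for ~20 s, sampled at 100 kHz) while a load cell records the
holding force. Stretching stops at the first level producing at least a 50%
drop in CAP amplitude, or at λ = 1.20. The pipeline turns these recordings
into (i) a per-specimen constitutive model, (ii) a per-specimen map from
stretch to percent CAP reduction, and (iii) cohort-level intervals and
tests.

## Signal chain

The raw trace is processed in four stages, in this order:

1. **Artifact gating.** Samples in a 0.5 ms window after each stimulus onset
   are replaced by linear interpolation across the window. The stimulus
   artifact is orders of magnitude faster and larger than the CAP; if it is
   left in place, the zero-phase band-pass smears its energy several
   milliseconds in both directions and biases the CAP peak, even though the
   peak search itself excludes the artifact window. Gating before filtering
   is standard stimulus-artifact suppression. A stimulus at the very first
   sample has no pre-onset anchor, so the bridge is flat from the first
   clean post-gate sample.
2. **Band-pass.** 4th-order Butterworth, 100–5000 Hz, applied
   forward-backward (`signal::filtfilt`). Zero-phase filtering is chosen so
   latency measurements are not shifted by filter delay.
3. **Per-sweep baseline subtraction.** The mean over the 5 ms immediately
   preceding each stimulus onset is subtracted from that sweep (the record
   is partitioned at the start of each baseline window, so every sample
   gets exactly one baseline). A stimulus too close to the record start
   gets a truncated window and a warning.
4. **Running median, 100 µs window** (11 samples at 100 kHz — the window is
   rounded up to an odd count for symmetry), suppressing single-sample
   spikes without moving the peak.

Epochs aligned on the stimulus onsets are truncated to a common length and
averaged. The CAP peak is the largest signed deflection after the 0.5 ms
blanking window (a `polarity` flag serves inverted montages); amplitude is
peak minus baseline and latency is the stimulus-to-peak delay. Peak picking
is automated rather than manual for reproducibility. Percent reduction is
(C₁.₀₀ − Cₙ)/C₁.₀₀ × 100, unclamped, so an amplitude increase shows up as a
negative reduction rather than being hidden.

Every stage after gating is linear or scale-equivariant, so on traces whose
waveform shape does not change with stretch the *reduction* is insensitive
to the (documented, ~5%) amplitude attenuation the band-pass inflicts on a
millisecond-scale biphasic waveform.

## Constitutive model

Cauchy stress under incompressible uniaxial extension is T₁₁ = f λ / A₀
(force N, area mm², stress MPa), with A₀ = π(d₀/2)² from the mean of the
diameter measurements, and the force per level taken as the maximum over
the stretch increment. The material model is the two-parameter polynomial
strain energy W = α(I₁−3) + β(I₁−3)², giving

T₁₁(λ) = [2α + 4β(λ² + 2λ⁻¹ − 3)] (λ² − λ⁻¹).

This response is linear in (α, β), so the least-squares problem has a
closed solution: the fit computes the unconstrained QR solution and, if it
violates the physical bounds α, β ≥ 0, enumerates the boundary solutions
(one parameter pinned at zero) — exact for a two-parameter problem, no
iterative optimizer involved. The objective is unweighted least squares on
Cauchy stress (weights are accepted if a user wants them); R² is reported
on stresses. Fits are returned as classed model objects with
`coef`, `predict`, `residuals`, `summary`, `plot` and `simulate` methods;
`extrapolate_curve()` evaluates the model densely beyond the tested range
and flags the extrapolated part.

## Stretch-to-reduction map and cohort intervals

A natural cubic smoothing spline is fitted to the per-trial
(λ, reduction) points by solving (I + μK)g = y with μ = (1−p)/p and K the
natural-spline roughness matrix; the curve is the natural interpolant of
the fitted values. The smoothing parameter p lives on [0, 1]: p = 1 is the
exact interpolating spline, p → 0 the least-squares line. The default
p = 0.9995 is near-interpolating; every calibration check in the package
uses p = 1 to remove this degree of freedom, since the exact value used in
comparable analyses is never reported.

Inversion (`stretch_at_reduction`) returns the *first* crossing of the
target level — the stretch needed to first produce a given reduction —
found by a 4096-point bracket scan plus bisection to |curve − target| ≤
1e-9; curves are never extrapolated for inversion. Cohort intervals at
reductions 0, 2.5, …, 50% use the Student-t half-width t₀.₉₇₅,ₙ₋₁·s/√n
(t rather than normal, because n ≈ 7); levels where fewer than two curves
contribute are reported missing rather than fabricated, with the dropped
count logged in the table.

## The reduced finite-element rod

Uniaxial tension of an incompressible isotropic rod is statically
determinate: the axial force is the same in every cross-section, so
equilibrium decouples into one scalar equation per element,
T₁₁(λₑ)·A₀ₑ/λₑ = F, solved by safeguarded Newton (numeric derivative,
bisection fallback, bracket [1, 1.5], |residual| ≤ 1e-10 N, ≤ 100
iterations). This reduction is deliberate: it captures the axial problem
exactly, is testable against closed forms to machine precision, and needs
no meshing decisions that could not be justified from the data. Stretch
control wraps a scalar root solve on F so the length-weighted mean element
stretch matches the prescribed value to ≤ 1e-9, then polishes with secant
steps. CAP reduction is mapped onto elements by *linear* interpolation of
the curve sampled at 0.001 stretch steps (matching how such maps are
applied in practice); stretches above the calibrated range clamp to the
boundary value by default (alternatives: `error`, `linear` extension), and
below it map to 0. The VTK export writes the deformed configuration —
node positions advanced by cumulative element stretches, radius scaled by
λ^(−1/2) per isochoric kinematics — with stretch, stress and reduction as
cell data; volume is conserved identically by construction.

What the rod does **not** model: bending, shear, transverse grip effects,
viscoelasticity, and any genuinely 3-D stress concentration. Nonuniform
geometries are equilibrated exactly, but the kinematics remain uniaxial
per element.

## Fiber angles

Angles are normalized to zero mean per section (plain arithmetic mean —
fibers cluster around the axis well inside ±90°, so no circular statistics
are needed), pooled across the three sections per nerve (a per-section
alternative is a one-line change upstream), binned into half-open 1°
bins, and summarized by FWHM: half the peak bin percentage, crossings
found walking outward from the peak with linear interpolation between bin
centers. No kernel smoothing is applied — the estimator works on the raw
histogram. Tukey fences (Q1 − 1.5·IQR, Q3 + 1.5·IQR, type-7 quantiles —
the linear-interpolation convention; others selectable) screen
per-specimen FWHM values within each group before a two-sided F-test
chooses between the pooled and Welch t-test at the 0.05 level.

## Synthetic cohorts: what they emulate, and what they do not

The generator reproduces the *statistical structure* the analysis assumes:

- Geometry and material truth drawn uniformly from the measured cohort
  ranges — diameter 1.30–1.53 mm, length 24.7–35.2 mm, α 0.037–0.31 MPa,
  β 0.78–3.40 MPa.
- A logistic reduction-vs-stretch truth R(λ) = 100·σ((λ−λ₅₀)/w), re-anchored
  so R(1) = 0 exactly and R(λ₅₀) = 50 exactly. Only the endpoints of the
  true dose–response are constrained by observation (0% at λ = 1, ≥50% by
  λ = 1.2), so any smooth monotone family would do; the logistic has two
  interpretable parameters. The re-anchoring makes the supremum exceed 100
  marginally in the far tail (beyond λ ≈ 1.33 at default width), so the
  output is capped just below 100. λ₅₀ is normal with mean 1.108 and
  between-specimen sd 0.0281 — the spread implied by a 95% CI half-width
  of 0.026 at n = 7 — and width w = 0.02, which spans the observed 0–100%
  transition over roughly λ 1.05–1.17.
- Traces: floor(duration × rate) + 1 stimulus epochs starting at t = 0; per
  epoch a rectangular 5 mV artifact of the stimulus duration, a biphasic
  CAP template (difference of two Gaussians, σ = 0.2/0.3 ms, 0.5 ms apart,
  normalized to unit peak) at latency = (L₀/2)/v, and additive white
  Gaussian noise. Electrode distance is taken as L₀/2 and conduction
  velocity defaults to 10 m/s — neither is measured in this preparation;
  10 m/s is representative of the slower myelinated contribution and puts
  the peak (~1.4 ms) well clear of the artifact window.
- Forces from the ground-truth constitutive response with mean-one
  multiplicative lognormal noise (positive forces by construction; the
  reference state stays exactly zero).
- Fiber angles from a wrapped normal with sd = FWHM/(2√(2 ln 2)); control
  FWHM 14°, stretched 8°, between-specimen sd 1°, 2000 fibers per section,
  three sections per nerve.

Passing the end-to-end checks on these cohorts shows the *pipeline* is
correct and calibrated under its own assumptions. It does not show that
real nerves have logistic dose–response curves, Gaussian-difference CAPs,
stationary noise, or stretch-independent waveform shape — on real data the
spline map exists precisely because the functional form is unknown, and
amplitude measurements inherit whatever artifact overlap and drift the
recording carries.

## Numerical conventions and problem sizes

Units are N, mm, MPa, mV, s (ms for latency) throughout. All generators
are deterministic given a seed; cohort-level seeds derive sub-seeds
through a fixed 32-bit map so results are independent of evaluation order.
The calibration studies shipped with the package use 50 specimens for the
fit-vs-normal-equations comparison, 200 seeds for noisy parameter
recovery, 200 cohort replicates (n = 7) for interval calibration, 200
replicates for fiber-group power, and 10⁵ draws for the FWHM consistency
check — sizes chosen so Monte-Carlo error is small against the tolerances
being checked.

## Known limitations

- Successive stretch trials on one nerve may accumulate damage; the model
  treats levels as independent measurements of one monotone curve.
- No viscoelasticity or rate dependence anywhere (the stretch protocol is
  quasi-static at 0.1 mm/s).
- The cohort intervals are plain per-level t-intervals, not a hierarchical
  model; specimens contribute independently at each level.
- The FWHM estimator is bin-resolution limited (1°) and assumes a unimodal
  histogram; multimodal fiber populations would need a different summary.
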