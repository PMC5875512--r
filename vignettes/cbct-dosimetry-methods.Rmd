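---
title: "Methods: point dose, dose line integrals and DLP_CBCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: point dose, dose line integrals and DLP_CBCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbctdose)
```

## The measurement problem

Kilovoltage CBCT on a linear accelerator delivers imaging dose over fields
up to ~28 cm long. A point dose at the phantom centre says nothing about
how much total energy the scan deposits, and the 100 mm pencil-chamber
CTDI concept undercounts both the central dose and the scatter tails for
beams this wide. `cbctdose` implements a two-part characterisation:

- an absolute point dose *D*~w~ (TG-61 in-water formalism) at the centre
  and at four peripheral positions of a phantom, reported in cGy per
  100 mAs;
- the full longitudinal dose profile at the depth of each measurement
  position, CAX-normalised, rescaled to the point dose and integrated into
  a dose line integral (DLI, mGy·cm per 100 mAs).

The two are combined with the CT-style radial weighting

$$\mathrm{DLP_{CBCT}} = \tfrac13\,\mathrm{DLI_{centre}} +
\tfrac23\,\mathrm{DLI_{periphery}},$$

a convex combination that estimates the average line integral across the
phantom cross-section. Because tube output is linear in mAs over the
clinical range, all quantities are tabulated per 100 mAs and scaled by
`total mAs / 100` to predict any protocol on a characterised system.

Assumptions worth keeping in view: the 1/3 : 2/3 weighting is inherited
from cylindrical CTDI phantoms and is unproven for oval cross-sections;
peripheral and central profile *shapes* are treated as interchangeable
(supported by chamber pairs matching within ±5% in validation
measurements, and exploited to halve the measurement burden); and
per-100-mAs normalisation assumes strict mAs linearity.

## TG-61 chain

`corrected_reading()` forms
$M = \bar M_{raw}\, k_{TP}\, P_{pol}\, P_{ion}\, k_{elec}\, k_{extra}$
with the standard kV forms:

- $k_{TP} = \frac{273.2+T}{273.2+T_0}\cdot\frac{P_0}{P}$, reference
  conditions 20 °C / 101.325 kPa (overridable);
- $P_{pol} = (|M^+|+|M^-|)/(2|M_{used}|)$;
- continuous-beam two-voltage recombination
  $P_{ion} = \frac{(V_H/V_L)^2-1}{(V_H/V_L)^2 - M_H/M_L}$, rejected as
  out-of-model when $M_H/M_L \ge (V_H/V_L)^2$.

These correction forms are standard kV dosimetry practice; the package
documents them explicitly because published dose tables rarely print them.
*N*~K~ is interpolated **linearly in first HVL** between calibration knots:
chambers of this class vary by <2% across the kV range, so the
interpolation scheme is immaterial; extrapolation is clamped to the end
knot and only allowed within 5% of the table span, otherwise a range error
names the valid interval. Field-size/depth corrections relative to TG-61
reference conditions are machine-specific and are deliberately exposed as
one user-supplied multiplicative `extra_correction` (default 1) rather
than reproduced from any particular lookup.

HVL itself (`estimate_hvl()`) is log-linear interpolation of
ln(transmission) to the 50% crossing, after rescaling the series to its
zero-thickness reading; an exactly-0.5 sample short-circuits to its
thickness, and non-monotonic or non-bracketing series are errors rather
than guesses.

## Profile processing

Positions are millimetres along the scan axis with the isocenter at 0.
The processing chain and its decisions:

- **Calibration** (`calibrate_array()`): in a sweep every diode sees the
  same beam portion, so reference-corrected readings estimate relative
  sensitivities; factors are 1/sensitivity normalised to mean 1. The
  mean-1 convention leaves a harmless scan-wide scalar that CAX
  normalisation removes.
- **Output correction** (`reference_normalize()`): one multiplicative
  tube-output factor per scan, recorded by a stationary reference diode —
  scans are divided by the ratio of their reference reading to the first
  scan's. Drift is modelled (and corrected) per scan, not per frame,
  matching how a reference diode is actually used.
- **Stitching** (`stitch_scans()`): shifted acquisitions are superimposed
  by rescaling each incoming scan with a single least-squares scalar over
  its overlap (≥3 samples) with the accumulating merge, then averaging
  coincident positions (1 µm tolerance). A scalar is the right model
  because between-scan differences are multiplicative (tube output);
  a post-fit overlap residual above 5% of the central value signals a
  non-multiplicative contradiction and raises a warning. Non-overlapping
  regions keep the scan's values unchanged apart from that one scalar.
- **Central value** (`central_value()`): linear interpolation at x = 0.
  The centred 88-diode array has no detector on the axis (samples at
  ±2.5 mm, ±7.5 mm, …); for flat-topped CBCT fields the interpolation
  error is far below measurement noise. Averaging the two central diodes
  would be equivalent for symmetric profiles but wrong for asymmetric
  ones, so it was rejected.
- **Comparison** (`compare_profiles()`): pointwise deviations are
  expressed as % of the CAX value, not of the local value — tails near
  zero would otherwise blow up the metric — and the area difference uses
  trapezoidal areas over the common extent (required to cover ≥80% of the
  shorter profile).

## DLI and DLP

`to_absolute()` multiplies a relative profile by 10 × the point dose
(cGy → mGy); `integrate_dli()` is the trapezoid rule on the measured grid
with mm → cm conversion. **No tail extrapolation** is performed beyond the
measured span: the span is recorded as `truncation_extent_mm` in results
so protocols measured with different spans are only compared knowingly.
One measured profile shape per collimator serves both radial positions;
the peripheral DLI is the central shape rescaled by the ratio of average
peripheral to central point dose.

DLIs and DLP are reported at 1 decimal, point doses at 2 decimals, with
full precision retained internally. Published tables round their
intermediates, so consistency checks against printed DLP values use a
0.2% tolerance.

## Protocol engine

Collimator codes (S/M/L × 2/10/15/20) map to fixed FOV widths
(276.7 / 426.4 / 524 mm) and field lengths (35.2 / 135.4 / 178.7 /
276.7 mm). The dose table is keyed by (phantom, kVp, rotation class,
collimator); rotation classes are `full` (arc within 10° of 360°) and
`half` (within 30° of 200°), and any other arc is rejected rather than
interpolated — peripheral dose varies strongly around the circumference
during a partial rotation, so interpolation would be unfounded. Phantom
selection is site-driven (head → head phantom, chest/pelvis/prostate →
body), falling back to kVp (100 → head, 120 → body), so new sites can be
mapped without code changes.

Per-100-mAs entries are rotation-class-specific for point doses, while the
DLI pair is shared per collimator (one published profile integral per
collimator; per-100-mAs doses are rotation-normalised because total mAs is
proportional to arc). The predicted DLP is recomputed from the entry's
DLIs — never read from a stored DLP column — so every report satisfies the
1/3 : 2/3 identity to machine precision. Protocols with kVp or filters
outside the table raise an error advising new measurements instead of
extrapolating; only the open F0 filter is supported.

The bundled Elekta XVI reference table (see `inst/extdata/PROVENANCE.md`)
ships as replaceable fixture data and is never silently mixed with user
measurements. Where the published record is internally inconsistent in its
last digit (the chest-protocol DLP appears as both 665.1 and 665.2
mGy·cm), the fixtures carry 665.1.

## The instrument simulator

`ground_truth_beam()` models a profile as a Gaussian-blurred rectangle
(width *L*, blur σ) plus a scatter plateau of fraction *f* under the field
decaying exponentially (length λ) beyond the edges:

$$\int D(x)\,dx = A(1-f)L + fA(L+2\lambda),$$

exactly. This functional form was chosen over more physical models
precisely because the closed-form integral gives an independent oracle for
every downstream integration; visually it reproduces the rounded top and
long tails of measured kV CBCT profiles. Defaults (L = 178.7 mm, σ = 6 mm,
f = 0.12, λ = 40 mm, A = 3.1 mGy/100 mAs at 15 cm depth, 120 kVp) mimic a
"15"-length collimator field in a body phantom: σ and λ are set so the
simulated 440 mm array cannot quite capture the tails, forcing the
three-scan stitching path that real long-field measurements need; f is a
typical deep-phantom scatter plateau; A equals the bundled M15 central
dose.

Noise (all relative, Gaussian): per-diode sensitivity sd 0.03, per-reading
sd 0.005, per-scan tube drift sd 0.01. These defaults are plausible for a
clinical diode array with a drifting kV tube and are the conditions under
which the validation properties are asserted. One integer seed drives a
campaign; sub-streams are derived deterministically (sensitivities shared
across all simulations with the same noise model, per-scan drift and
reading noise by scan index), so identical inputs give bit-identical
campaigns and the simulators never disturb the caller's RNG state.

What the simulator does **not** emulate: detector dead time, temperature
response, energy dependence of diode sensitivity, gantry-angle-resolved
dose, bone heterogeneity, or any spectral physics. Passing the simulated
round trips therefore demonstrates the *processing chain* is correct and
stable under realistic noise — not that any physical beam matches the
model. Correspondingly, measured quantities that live in the physics (the
5.75 / 6.80 mm Al HVLs of real 100 / 120 kVp beams) are not reproducible
in simulation and are not asserted anywhere; the HVL tests check the
estimator against exact exponentials across μ = 0.08–0.20 /mm.

## Problem sizes and numerical tolerances in the test suite

- Zero-noise round trips: TG-61 chain to 1e-10 relative; an 88-diode,
  three-scan campaign against the CAX-normalised beam to 1e-9; dense-grid
  (1 mm) DLI against the closed form within 0.5%, with halving the grid
  moving the result by <0.1%.
- Stochastic validation mirror: 100 campaigns at default noise, each
  compared with a noiseless 2 mm chamber scan; the maximum pointwise
  deviation must stay below 3% of CAX in at least 95 of them. This mirrors
  the ±3% array-vs-chamber agreement reported for 8 cm depth validation
  measurements, as a simulation property.
- Distributional check: recovered sensitivity spread within [0.02, 0.04]
  across 20 seeds; 30-repeat Monte Carlo of noisy reading sets recovering
  the mean dose within 0.5%.

These sizes keep the whole suite under ~10 s while leaving each assertion
far from its tolerance under the stated conditions.

## Known limitations

- The half-rotation table entries redistribute dose around the periphery
  in reality; the average-periphery figure hides that, and organ-specific
  conclusions near a half-arc's entry/exit need angular measurements.
- DLI truncation at the measured span slightly undercounts very long
  tails; the recorded `truncation_extent_mm` is the honest scope of the
  integral.
- Bone doses are substantially higher than dose to water at kV energies;
  all reported values are absorbed dose to water.
- Effective dose and organ doses are out of scope: `integral_dose()`
  (DLP × cross-sectional area × density) is as far as the package goes
  toward energy-imparted metrics.
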