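---
title: "Comparing OPM sensor-array designs by simulation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing OPM sensor-array designs by simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opmsim)
```

## The question and the simulation design

Optically pumped magnetometers (OPMs) can sense the magnetic field along
one, two, or three orthogonal axes at a single scalp location. With a fixed
budget of recording channels, a whole-head system can therefore be built as
many monoaxial sensors, fewer biaxial sensors, or fewer still triaxial
sensors. Radial (surface-normal) channels pick up the most signal from
brain sources, but tangential channels sample the ambient interference
field in directions the radial channels miss, which matters once the
wearer's head — and with it the sensor array — moves through the residual
static field of a shielded room.

`opmsim` implements a complete simulation pipeline to quantify this
trade-off at a fixed channel count of 192:

1. build a monoaxial (192 locations), biaxial (96) or triaxial (64)
   array on a half-ellipsoid head surface;
2. simulate recordings of a tangential current dipole whose signal is
   present in every even-numbered sample ("active" columns) and absent in
   odd-numbered ones ("baseline" columns), superposed on sensor noise,
   distributed brain noise, and movement-induced ambient interference;
3. clean each data segment with one of several standard interference
   suppression methods;
4. fit an equivalent current dipole to the active-minus-baseline average
   of each segment and record the localization error and the fitted
   moment magnitude;
5. aggregate medians and interquartile ranges per (array, noise,
   cleaning) condition.

## Geometry and forward model

The head is an axis-aligned ellipsoid with full cardinal axes 15 cm
(left–right), 18 cm (posterior–anterior) and 16 cm (inferior–superior),
centered at the coordinate origin; the brain compartment is the upper half
of a concentric ellipsoid with axes 12.9/15.4/13.7 cm. Sensor locations
are placed with a Fibonacci (golden-angle) lattice on the upper unit
hemisphere, mapped onto the head by anisotropic scaling — a deterministic,
quasi-uniform rule (nearest-neighbour spacing varies by under 30%). The
half-step offset of the lattice keeps every location strictly off the
pole, where the azimuth is undefined (at the pole the azimuthal direction
falls back to +x). Sensors sit exactly on the surface: no standoff is
modeled, which maximizes both signal and the spatial-frequency content the
cleaning methods must cope with.

Channel orientations come from the local surface frame: the radial
direction is the outward normal of the implicit ellipsoid function, the
azimuthal direction is `normalize(z × radial)`, and the polar direction
completes the right-handed triad. Biaxial locations alternate their
tangential axis between azimuthal and polar, giving 48 channels of each.

The volume conductor is a homogeneous sphere centered at the ellipsoid
center, evaluated with the closed-form current-dipole field. The closed
form is analytic, fast, and makes the radial source direction *exactly*
silent, which pins down the "silent frame" used to orient the simulated
dipoles: the right-singular vectors of the local 192×3 leadfield, with z'
the weakest-gain (most radial) direction, sign-aligned outward, and x'/y'
spanning the tangential plane in decreasing-gain order. A sphere rather
than a realistic shell is a deliberate simplification; it shifts absolute
sensitivity ratios and localization numbers by modest amounts but leaves
the comparisons between arrays — which all share the conductor — intact.

Source grids are axis-aligned lattices that include the origin as a
lattice point, keep points strictly inside the region ellipsoid and in its
upper half *including* the equatorial plane (z ≥ 0). With this convention
the 2.5 mm sensitivity grid holds 46,870 points; the convention was chosen
because plausible alternatives (strict z > 0) change the count by ~5%.
The signal grid uses 10 mm spacing with z ≥ 20 mm (481 locations); the
brain-noise grid uses 6.3 mm spacing.

## Noise generators

**Sensor noise** is i.i.d. Gaussian per channel and sample with a 2 pT
standard deviation (equivalently 200 fT/√Hz in a 100 Hz bandwidth); a
doubled, 4 pT, variant probes the SNR scaling of localization error.

**Brain noise** is the superposition of dipoles at every 6.3 mm grid
location with i.i.d. Gaussian moments (SD 1 nAm per Cartesian component,
white over time). Because a linear map of white noise is fully described
by its covariance, the generator draws directly from the exact channel
covariance σ²LLᵀ through a symmetric factor instead of materializing the
~8,000-source moment time series; the distribution is identical and the
cost drops by three orders of magnitude.

**Movement noise** emulates wearing the array in the residual DC field of
a shielded room. The static field is synthesized as the gradient of a
random real harmonic polynomial potential of degree ≤ 3 — physically valid
(divergence- and curl-free) uniform, constant-gradient and
constant-curvature terms — with the three degree groups rescaled so the
map reproduces three published summary statistics of a measured room:
mean |B| = 50.1 nT, mean first-order gradient 6.7 nT/m, and mean
second-order gradient 35.6 nT/m². Gradients are measured as the mean
Frobenius norm of the finite-difference derivative tensors on the map's
own lattice (3 vertical planes 23 cm apart; 5 cm × 10 cm in-plane spacing,
±15 cm extent). Curvature terms alone already produce a first-order
gradient; an occasional random draw is so gradient-heavy that the 6.7 nT/m
target cannot be reached with non-negative group scales, in which case the
coefficients are redrawn deterministically.

Head motion is a rigid-body trace at 10 Hz (6,000 samples ≈ 10 min):
per-axis translations and rotation angles are smoothed Gaussian random
walks (moving-average window = 2 s), zeroed at t = 0 and rescaled to a
5 mm / 1° SD. The rotation amplitude was calibrated so that the
per-channel ambient signal SD of a head-mounted triaxial array lands near
the published 0.5–0.7 nT with peak-to-peak fluctuations of a few nT.
Projection onto the moving array evaluates the field map at each sensor's
rotated-and-translated position via tensor-product interpolating cubic
B-splines (natural end conditions; queries outside the box are clamped
and counted) and takes the dot product with the rotated orientation.
`motion_from_coils()` converts recorded positions of three head coils
into the same rigid-transform representation (orthogonal Procrustes,
circumcenter reference), so measured motion can substitute for the
synthetic walk.

What the surrogate does *not* emulate: the measured map's spatial
structure beyond second order. A degree-3 harmonic polynomial calibrated
to the printed averages is very smooth; position-dependent pickup during
translation is then tiny compared with rotation through the 50 nT uniform
component. Two consequences, verified by the experiment drivers: the
uniform-field variant (componentwise median map) performs essentially the
same as the full map here, whereas with a measured room map the
non-uniformity costs extra accuracy; and absolute movement-condition
numbers are meaningful only as orderings across arrays and methods, not
as field-strength-faithful values.

## Cleaning methods

All methods consume one 600-sample segment (recordings are cut into 45
windows with 80% overlap; the even step preserves column parity) and
return a cleaned active-minus-baseline topography.

* **Baseline subtraction** — the plain average difference; removes any
  static field exactly.
* **HFC** — least-squares regression on the external (regular solid
  harmonic) field models up to degree 1 or 3 about the head center; the
  degree-1 basis is exactly the three orientation-component columns, so
  uniform interference cancels to machine precision. The projector is
  symmetric and idempotent and commutes with averaging.
* **tSSS** — joint least-squares split into internal (irregular
  multipoles, degree ≤ 8) and external (regular, degree 1 or 3) models;
  the internal reconstruction is kept, and temporal directions whose
  principal-angle correlation between the two reconstructions exceeds
  0.98 are projected out.
* **DSSP** — spatial split by the leading left-singular subspace of the
  signal-grid leadfield (99% energy); temporal directions common to the
  inside and outside parts (correlation > 0.95) are projected out of the
  full data.
* **AMM** — internal irregular multipoles to degree 8 plus an adaptive
  external subspace formed from the leading principal components of the
  residual (≥ 99% energy, at most 10 components; automatically orthogonal
  to the internal model), with the same temporal step. The spheroidal
  refinements of the original method are not implemented, which we flag
  as a fidelity limitation.
* **LCMV** — per-segment minimum-variance beamformer over the signal
  grid, diagonal loading 0.05 × mean covariance diagonal. Per grid point
  the statistic is the maximum over orientations of the active-to-
  baseline output power ratio (a pseudo-F). The power *difference* was
  also considered, but with a smooth surrogate field its interference
  sampling noise overwhelms the pT-scale signal and the scan peaks at
  spurious deep points; the ratio cancels class-common interference and
  is the conventional active-versus-control beamformer contrast.

Two numerical guards matter in the temporal projections. First, temporal
bases keep only singular vectors above 10⁻⁸ of each part's largest
singular value. Second, a candidate common course is removed only if the
external part carries at least 1% of the internal part's energy along it.
Without the second guard a *noise-free* dipole is annihilated: its only
"external" content is truncation leakage, which correlates perfectly with
its internal course. The guard distinguishes leakage (tiny external
energy) from genuine interference (comparable energy on both sides).

The zero-standoff geometry caps what any internal multipole model can
represent: a source millimetres below a sensor has harmonic content far
above degree 8, and raising the order degrades the basis conditioning
faster than it helps (the basis pseudo-inverses use a 10⁻⁸ relative
singular-value cutoff, with condition numbers reported). Internal
reconstruction is accurate for sources in the inner half of the brain
volume and degrades towards the surface; tests assert the preservation
property in the region where the model is valid. The forward model used
for dipole fitting is *not* modified by any cleaning projector — fits are
biased by design where a method distorts the topography, matching how
such pipelines are typically run.

## Dipole fitting and metrics

Each topography is fitted with a Nelder–Mead simplex over the dipole
position (5 mm initial steps, relative objective tolerance 10⁻⁴, at most
2,000 evaluations), starting at the true source location — an initial
grid search adds cost without accuracy here. The objective is the
residual fraction after the optimal linear moment, computed by truncated
SVD so the exactly-silent radial direction cannot inflate the moment.
Positions leaving the head ellipsoid are penalized smoothly
(1 + 10³ × surface distance), keeping the simplex well-defined without a
hard constraint. Outcome metrics are the Euclidean position error in mm
and the moment norm in nAm; summaries use medians and 25th–75th
percentiles with the linear-interpolation quantile definition.

## Experiment orchestration and problem sizes

`run_experiment()` crosses arrays × noise condition × cleaning methods.
Every recording gets noise seeds derived deterministically from the
master seed and the (array, location, orientation) indices, so results
are bit-reproducible and independent of evaluation order. Failed fits
are excluded and counted (none occur under the default conditions).

Default analysis scale, chosen to keep each driver in the minutes range
on a single core: 100 signal-grid locations × 2 tangential orientations ×
45 segments per array for the sensor-noise conditions, and 30 locations
with every third segment (15 per recording) for the movement conditions,
where per-segment SVD-based cleaning dominates the cost. Medians over
900+ fits per condition are stable to well under the effect sizes of
interest; running all 481 locations only sharpens the quantiles.

## Known limitations

* The spherical conductor understates tangential-channel gains relative
  to realistic single-shell models; the radial/tangential sensitivity
  ratio carries a corresponding model uncertainty.
* The ambient surrogate is spectrally poorer than a measured room map
  (see above); movement-condition results are orderings, not absolute
  predictions, and the uniform-field variant shows almost no contrast to
  the full map.
* Multi-axis sensors are modeled with the same 2 pT noise per channel;
  the extra noise of reading several axes from one cell, cross-axis
  projection errors, and gain/orientation drift are out of scope.
* Temporal structure is limited to the active/baseline alternation; no
  oscillatory sources or physiological artifacts are simulated.
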