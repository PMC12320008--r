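# opmsim

Simulation framework for a design question in wearable
magnetoencephalography (MEG): given a fixed budget of recording channels,
should an on-scalp optically-pumped-magnetometer (OPM) array use many
monoaxial sensors, fewer biaxial sensors, or fewer still triaxial sensors?
Radial (surface-normal) channels are the most sensitive to brain sources,
but tangential channels sample the ambient interference field that couples
in when the wearer moves through the residual static field of a shielded
room.

`opmsim` builds three synthetic 192-channel arrays on a half-ellipsoid
head — 192 monoaxial, 96 biaxial, or 64 triaxial sensors — and runs a
factorial simulation study over them:

* **Forward model**: current dipoles in a homogeneous spherical conductor
  (closed-form field), leadfields, and a Gram-matrix sensitivity analysis
  `diag(L Lᵀ)/N` over a dense 2.5 mm dipole grid in the brain compartment.
* **Signals**: 10 nAm tangential dipoles whose topography is added to
  every even-numbered sample of a 6,000-sample recording, so odd columns
  are baseline and even columns are active observations.
* **Noise**: white sensor noise (2 pT, i.e. 200 fT/√Hz at 100 Hz
  bandwidth), spatially correlated brain noise from a 6.3 mm dipole grid
  (1 nAm SD), and movement noise — a synthetic rigid head-motion trace
  projected through a static ambient field map calibrated to a measured
  shielded room (mean |B| 50.1 nT, mean gradients 6.7 nT/m and
  35.6 nT/m²).
* **Cleaning**: baseline subtraction, harmonic field correction (HFC,
  orders 1/3), tSSS (external orders 1/3), DSSP, adaptive multipole
  modeling (AMM), and an LCMV beamformer scan.
* **Outcome**: per 600-sample segment, an equivalent-current-dipole fit
  (Nelder–Mead position search + linear moment) of the active-minus-
  baseline average; distributions of localization error (mm) and moment
  magnitude (nAm) summarized as medians and interquartile ranges.

## Worked example

Sensitivity analysis plus a small white-noise localization run:

```r
library(opmsim)

tri <- build_array("triaxial")
dense <- make_source_grid(2.5e-3)          # 2.5 mm grid, brain compartment
g <- gram_diagonal(grid_leadfield(tri, dense))
radial_tangential_ratio(g, tri)
#> [1] 2.651195

cfg <- experiment_config(
  arrays = c("monoaxial", "biaxial", "triaxial"),
  noise = "sensor", cleaning = "baseline",
  n_locations = 20, seed = 1)
ex <- run_experiment(cfg)
print(ex)
#> <opm_experiment> noise=sensor, 20 locations x 2 orientations
#>       array baseline
#> 1 monoaxial      3.6
#> 2   biaxial      4.5
#> 3  triaxial      5.0
```

The first number says a triaxial array's radial channels pick up, on
average, ~2.7× as much signal power from brain sources as its tangential
channels. The table gives the median localization error in millimetres
over 20 dipole locations × 2 tangential orientations × 45 noisy segments:
under pure sensor noise the monoaxial (all-radial) array localizes best,
and the advantage of tangential channels only appears once movement-
induced interference and spatial cleaning enter (see
`analysis/04_movement_noise.R` and `analysis/05_cleaning_comparison.R`).

The `analysis/` directory holds the numbered drivers for the full study —
array geometry and Gram sensitivity, white-noise and doubled-noise
localization, brain noise, movement noise with the uniform-field control,
and the cleaning-method comparison. Each writes its summary tables under
`results/`.

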