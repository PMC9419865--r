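# nanomech

Quantitative analysis of epithelial cell sheets grown on soft electrospun
nanofibrous culture membranes versus flat tissue-culture polystyrene
(TCPS) — for researchers doing bio-AFM nanoindentation, nanofiber
morphometry, cell-monolayer image analysis and scratch-wound assays on
such platforms.

The scientific core is a contact-mechanics model fit. A colloidal sphere
(radius *R*) indenting a live cell is modelled as classical JKR adhesive
contact in parallel with a membrane spring, plus instrument nuisance
terms:

```
F(a) = 4E*a^3/(3R) - sqrt(8 pi w E* a^3)      E* = E/(1 - nu^2)
d(a) = a^2/R      - sqrt(2 pi w a / E*)
F(z) = F_JKR(z - z0) + K_m (z - z0)_+ + b0 + b1 (z - z0)
```

`jkr_fit()` estimates the Young's modulus *E* (Pa), work of adhesion *w*
(J/m²), membrane stiffness *K_m* (N/m), contact point *z0* and baseline by
bounded nonlinear least squares on the approach segment, reports the
dimensionless membrane-to-bulk ratio `beta = K_m/(E R)`, and quantifies
adhesion from the retract segment (pull-off work via `F_pull = -1.5 pi w R`
and approach–retract hysteresis energy). It returns a classed model object
with `print`, `summary`, `coef`, `predict`, `plot`, `residuals` and
`simulate` methods.

Around that core the package provides, each with a synthetic-data
generator carrying exact ground truth:

* **Fiber-mat morphometry** — `segment_fibers()`, `fiber_diameters()`
  (skeleton + distance transform), `pore_sizes()`,
  `orientation_anisotropy()` (2D-FFT order parameter), `rq_roughness()`.
* **Cell morphometry** — `segment_nuclei()`, `segment_cells()`
  (nucleus-seeded propagation), `shape_features()` (area, perimeter,
  eccentricity, circularity, N:C ratio, mean grey),
  `internuclear_distances()`, `cell_height()`, `fold_change()`.
* **Wound kinetics** — `segment_wound()` (local-variance texture),
  `wound_kinetics()` (area fractions, closure time, per-front velocity).
* **Statistics & pipeline** — `compare_groups()` (paired / Welch t),
  `run_pipeline()` + YAML config for the full synthetic study
  (a thin CLI wrapper lives in `inst/scripts/nanomech-pipeline.R`).

## Worked example

Fit a synthetic cell-junction indentation curve whose true parameters are
*E* = 30.73 Pa, *w* = 1e-5 J/m², beta = 1.37 (*R* = 2.6 µm, 0.5 pN noise):

```r
library(nanomech)
truth <- contact_params(E = 30.73, w = 1e-5,
                        K_m = 1.37 * 30.73 * 2.6e-6, R = 2.6e-6)
curve <- gen_force_curve(truth, z_range = 1.4, n_points = 500,
                         noise_sd = 5e-4, contact_offset = 1, seed = 42,
                         region = "junction", substrate = "NCCI")
fit <- jkr_fit(curve)
print(fit)
#> JKR + membrane fit (junction on NCCI)
#>   E = 29.9 Pa, w = 1e-05 J/m^2, K_m = 0.000111 N/m, beta = 1.426
#>   z0 = 0.9990 um, rmse = 0.000485 nN, converged = TRUE
#>   adhesion: w_pulloff = 1e-05 J/m^2, hysteresis = -1.53e-20 J
```

The fitted modulus (29.9 Pa) and ratio (1.43) sit within the uncertainty
expected at this noise level; on a noise-free curve both return to truth
within a fraction of a percent. `plot(fit)` overlays data, fit and contact
point.

Wound closure from a synthetic series whose fronts advance at 10 µm/h
(360 µm initial scratch, imaged every 6 h, 3 replicates per time point):

```r
ws <- gen_wound_series(initial_width = 360, front_velocity = 10,
                       timepoints = seq(0, 24, 6), replicates = 3, seed = 1)
wound_kinetics(ws)
#>   time_h area_um2 fraction
#> 1      0   184400   1.0000
#> 2      6   122900   0.6666
#> 3     12    62340   0.3380
#> 4     18        0   0.0000
#> 5     24        0   0.0000
#>   per-front velocity: 10 um/h (gap closure 20 um/h)
#>   closure time: 18 h
```

The estimated front velocity recovers the generated 10 µm/h, and closure
is detected at the 18 h frame where the generated wound first reaches zero
width.

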