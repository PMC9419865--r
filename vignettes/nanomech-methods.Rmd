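---
title: "Models and methods behind nanomech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nanomech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

nanomech quantifies how epithelial cell sheets behave on soft electrospun
nanofibrous culture membranes compared to flat tissue-culture polystyrene
(TCPS): the mechanics of the cells probed by AFM nanoindentation, the
morphology of the fiber mat itself, the shape and junction-protein content
of the monolayer, and its collective migration in a scratch assay. This
vignette explains the models, the estimator choices, the synthetic-data
generators used for validation, and the package's known limitations.

## The contact-mechanics model

A colloidal spherical probe (radius $R$, here 2.6 µm) indenting a live cell
produces a force–displacement curve with three physical ingredients:

1. **Adhesive elastic contact.** We use the classical JKR
   (Johnson–Kendall–Roberts) model of a rigid sphere on an incompressible
   elastic half-space, parametric in the contact radius $a$, with
   $E^\ast = E/(1-\nu^2)$:
   $$F(a) = \frac{4E^\ast a^3}{3R} - \sqrt{8\pi w E^\ast a^3}, \qquad
     \delta(a) = \frac{a^2}{R} - \sqrt{\frac{2\pi w a}{E^\ast}}.$$
   $E$ is the bulk Young's modulus of the indented structure (Pa), $w$ the
   work of adhesion (J/m²). Setting $w = 0$ recovers Hertz contact,
   $F = \tfrac{4}{3}E^\ast\sqrt{R}\,\delta^{3/2}$. The minimum of $F(a)$
   along the branch is the pull-off force $-\tfrac{3}{2}\pi w R$.
2. **Membrane stretching.** The tensed cell membrane resists indentation
   like a linear spring: a term $K_m\,\delta$ (with $K_m$ in N/m) is added
   in the contact regime. The dimensionless membrane-to-bulk ratio is
   defined as $\beta = K_m/(E R)$ — the probe radius is the only natural
   length scale available to make the ratio dimensionless, and this
   convention is declared rather than inherited.
3. **Instrument frame.** An unknown contact point $z_0$ along the piezo
   axis and a linear force baseline (offset + drift) complete the model:
   $$F(z) = F_{JKR}(z - z_0) + K_m (z - z_0)_+ + b_0 + b_1 (z - z_0).$$

`composite_forward()` evaluates this model by numerically inverting the
parametric branch: $\delta(a)$ is strictly increasing above the loading
radius $a_0 = (2\pi w R^2/E^\ast)^{1/3}$ (and above the pull-off radius on
unloading), so a monotone (Hyman-filtered) spline over a 300-point
log-spaced grid in $a$ gives $F(\delta)$ to better than $10^{-3}$ relative —
an order below every fitting tolerance used.

### Contact-point estimation

The contact point must be inferred from the curve. The default
(`estimate_contact_point()`, method `"piecewise"`) grid-searches candidate
$z_0$ values: each candidate is scored by the SSE of a joint linear
least-squares fit of a baseline line plus an adhesionless contact basis
$\{\delta^{3/2}, \delta\}$ on the post-contact side. Because the basis is
linear in its coefficients this costs one `lm.fit` per candidate. If no
candidate beats 95% of the baseline-only SSE the curve is declared
contact-free. A ratio-of-variance detector (`"rov"`) is available as a
config alternative.

With adhesion the JKR force is discontinuous at first touch (a
jump-to-contact of $-\tfrac{4}{3}\pi w R$), which the adhesionless search
basis cannot represent; the grid estimate is therefore biased slightly
early on sticky curves. The full fit treats the grid value only as a
starting point and refines $z_0$ inside a ±0.2 µm box, which removes the
bias (the SSE landscape in $z_0$ is a smooth funnel on clean curves).

### Fitting strategy

`jkr_fit()` performs bounded nonlinear least squares on the approach
segment. The search is reduced to three dimensions — $(\log E,\ w,\ z_0)$ —
because at fixed values of those the model is linear in $(K_m, b_0, b_1)$,
which are profiled out by constrained linear least squares ($K_m$ clamped
to its bounds). Five deterministic starts (spanning soft/stiff and
adhesive/adhesionless corners around a jump-robust Hertz-slope initial
guess) feed L-BFGS-B, and the winner gets a fine-step polishing pass.
Default bounds are $E \in [0.1, 10^6]$ Pa, $w \in [0, 0.1]$ J/m²,
$K_m \in [0, 1]$ N/m, all config-overridable. Non-convergence is flagged on
the result, never silently dropped. On noise-free synthetic curves all
parameters return to truth within well under 1%; under 5% force noise the
median modulus error across seeds stays below 10%.

Fitting uses the approach segment only; adhesion is quantified from the
retract segment only. Two adhesion measures are always reported side by
side, because "adhesion energy" is ambiguous: `w_pulloff` converts the
depth of the retract minimum below the baseline via the JKR identity
$w = 2|F_{min} - b|/(3\pi R)$, and `hysteresis_energy` integrates the
approach–retract loop (trapezoidal, in J). The retract baseline is
estimated from the pre-contact stretch of the *approach* segment: for soft,
sticky samples the adhesive neck can persist far below the contact point,
so the retract's own far region is not reliably force-free. An optional
tip–sample separation correction ($\delta = z - z_0 - F/k$) is off by
default; the curves analysed here come with forces already converted via
the cantilever spring constant.

### Limitations of the contact model

The elastocapillary JKR refinement (surface-tension-dominated contact,
relevant when $\gamma/(E R)$ is large) is not implemented; at the moduli
and probe radius used here the classical large-body limit is assumed. The
model is quasi-static and purely elastic — no viscoelasticity, no thermal
drift correction. The membrane term is a phenomenological linear spring;
$\beta$ values are comparable within this convention only.

## Fiber-mat morphometry

* **Segmentation** — local-mean adaptive threshold (window 15 px, offset
  0.02), 3-px morphological closing, removal of components under 20 px.
  All parameters sit in the config.
* **Diameters** — Zhang–Suen thinning (compiled in the package) gives the
  skeleton; the diameter sample is $2\times$EDT at each skeleton pixel.
  Pixels within one local radius of a branch point are excluded so fiber
  crossings do not contaminate the sample; branch points are detected by
  the Hilditch crossing number (a raw neighbour count misfires on the
  staircase pixels of diagonal skeletons). No sub-pixel correction is
  applied: the discretization bias of $2\times$EDT is orientation
  dependent (about $+0.5$ px for axis-aligned ribbons, $-0.2$ px for
  diagonal ones) and averages out over randomly oriented mats. Skeleton
  pixels, not fibers, are the sampling unit of the reported distribution.
* **Pores** — connected components of the background, border-touching
  components excluded, equivalent diameter $2\sqrt{A/\pi}$. These are 2D
  projected pores; the mat's 3D tortuosity is out of scope.
* **Orientation** — Hann window, 2D FFT power spectrum, power integrated
  over an annulus (default 0.1–0.9 of Nyquist — wide enough to bracket the
  fiber-width frequency at any sensible magnification, config-exposed
  because no single right answer exists) into 180 angular bins. The order
  parameter $S$ is the resultant length of the power-weighted doubled-angle
  vector: 0 isotropic, 1 aligned. Spectrum angles are rotated 90° to
  real-space fiber orientation.
* **Roughness** — least-squares plane removal, then
  $R_q = \sqrt{\langle h^2 \rangle}$. Exactly zero for any plane; $A/\sqrt2$
  for a sinusoid.

## Cell morphometry

Nuclei: Gaussian blur, global Otsu, distance-transform watershed to split
touching nuclei, minimum-area filter. Cells: seeded propagation
(EBImage's `propagate`) of the nucleus labels over the smoothed actin
channel, constrained to the foreground mask — exactly one cell per nucleus,
the natural re-implementation of a seeded-watershed CellProfiler pipeline
whose exact parameters were never published; every parameter is exposed in
the config.

Shape features per object: area, perimeter, eccentricity
$e = \sqrt{1 - (\lambda_{minor}/\lambda_{major})^2}$ from the second-moment
ellipse (a $1/12$ pixel-patch term is added to the central moments so a
single pixel has the moments of a unit square), compactness (circularity)
$4\pi A/P^2$, equivalent diameter, centroid, mean grey. The perimeter is
the polygon length through every 4th traced contour point: plain chain-code
lengths overestimate smooth boundaries by ~5% while corner-corrected
weights underestimate polygonal ones, and the subsampled polygon is the
simplest estimator accurate for both a digital disc and a square.
Compactness is defined so that 1 = circle and *higher means rounder*; this
direction is a recorded convention. Eccentricity keeps its standard
direction (0 = circle); readers comparing "eccentricity closer to 1 means
more equiaxial" claims should use the axis ratio columns instead, which are
reported alongside. Nucleus-to-cell matching is by containment of the
nucleus centroid.

Cell height from a height map is (99th percentile of foreground heights)
minus (histogram mode of the substrate); from a confocal z-stack occupancy
mask it is (top occupied slice − substrate slice) × slice spacing. Both
estimators exist because AFM and confocal heights are comparable but not
identical; results should record their source.

Intensity fold change between two groups of per-cell mean greys is the
ratio of group means with a seeded bootstrap percentile CI.

## Wound kinetics

Frames are segmented by local variance: a confluent cell field is
high-variance texture, the denuded scratch is low-variance. The threshold
is Otsu on the *variance* map — variance mixes linearly as the box window
slides across the wound edge, so the midpoint threshold places the
boundary at the true edge (thresholding the SD map instead biases the
wound smaller by a fifth of the window width per side). The wound is the
largest low-variance component spanning at least half the scratch axis; a
candidate is rejected unless the outside/inside median local-SD ratio
exceeds 2, and a frame with no texture contrast at all (1st/99th local-SD
percentiles within a factor 2) is classified globally — all wound below
an absolute texture floor (default local SD 0.05 grey), confluent above
it — so fully closed and fully open frames both behave.
Areas are averaged over replicate images per timepoint, fractions are
normalized to $t=0$ (exactly 1 there by construction), and the migration
velocity is per advancing front:
$v = [W(t_i) - W(t_{i+1})]/[2(t_{i+1}-t_i)]$ with $W$ = area / wound
length along the scratch axis. The total gap-closure rate ($2v$) is also
emitted, since published "migration velocity" panels rarely state which
convention they use; per-front is primary here because it matches the
kinematics of two fronts advancing into the gap.

## Statistics

`compare_groups()` implements the paired t-test ($t = \bar d/(s_d/\sqrt n)$,
df $= n-1$) and Welch's unpaired test with Welch–Satterthwaite df.
Degenerate inputs are flagged: identical paired groups give $t=0, p=1$;
zero-variance nonzero-mean differences report $p$ at the machine-precision
bound rather than a fabricated number. The pipeline defaults to the paired
test to mirror the study design it reproduces, although between-substrate
comparisons are arguably unpaired — both are implemented and
config-selected. No multiple-testing correction is applied by default
(none was described for the original analyses); Holm adjustment of the
comparison table is one `p.adjust` call away.

## Synthetic data and what passing tests mean

Every generator returns its artifact plus a `ground_truth` record (kind,
parameters, seed, per-object truth table) and is bit-reproducible under
its seed without touching the global RNG.

* Force curves come from the same composite forward model the fitter uses,
  plus Gaussian force noise and linear drift. The default study cohort
  (`default_config()`) uses a 2% relative force noise, 1.4 µm of travel
  with contact at 1 µm, and per-region moduli spanning the soft-cell range
  (15–400 Pa).
* Fiber mats are straight full-image chords with normally distributed
  widths and axially von Mises orientations, anti-aliased, max-blended.
  Straight fibers keep the per-fiber truth analytic; real electrospun
  fibers curve, so real-image diameter estimates inherit an extra
  tracing error the tests cannot see.
* Monolayers are non-overlapping ellipses (closed-form area/eccentricity
  truth) with concentric elliptical nuclei and per-cell lognormal
  intensity variation. Real cells tile space and share boundaries; the
  seeded propagation is exercised more gently here than confluent tissue
  would.
* Height maps: tilted plane (zero intrinsic roughness), sinusoid
  ($R_q = A/\sqrt2$), or smoothed Gaussian field that is plane-removed and
  rescaled so its $R_q$ equals the requested amplitude exactly.
* Wound series: high-variance cell texture vs low-variance band narrowing
  at $2 v t$ — matched to the variance-based segmentation by design, which
  is precisely why passing says "the estimator recovers its own model" and
  not "brightfield wounds are this easy".

Acquisition noise levels were never reported for any of the instruments
emulated, so the generator defaults above are the package's own choices,
exposed in every signature.

## Numerical choices and problem sizes

Pixel-lattice work uses R's 1-based indices with pixel-center coordinates;
areas are pixel counts × pixel\_size². The test suite and the acceptance
script run the study at desk scale: 300–500-point force curves, a
100-seed noise study, one 2048-px fiber mat (200 fibers), 30-cell
monolayer images, and 10⁴ Monte-Carlo replicates for the type-I error
check — sizes chosen so the whole validation runs in minutes on one core
while keeping Monte-Carlo error well inside every tolerance it is compared
against.
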