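---
title: "Modelling leaf bidirectional reflectance with leafbrdf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling leaf bidirectional reflectance with leafbrdf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafbrdf)
```

## The problem

How a leaf redistributes the light it does not absorb shapes the light
climate of every leaf below it. A leaf surface is neither a mirror nor a
perfect diffuser: reflected light is the sum of a broad Lambertian background
and a specular lobe concentrated around the mirror direction, and the balance
between the two differs across species, canopy layers, and the adaxial
(upper) versus abaxial (lower) surface. `leafbrdf` implements a complete
chain for quantifying and predicting this behavior:

1. reduce angular reflectance scans from a goniometer-style instrument to
   calibrated bidirectional reflectance (BRDF, in sr^-1^);
2. fit a three-parameter Cook–Torrance microfacet model per wavelength;
3. measure leaf-surface roughness from cross-section micrographs;
4. predict the optical parameters from ordinary phenotypic traits with a
   stacking ensemble;
5. propagate the fitted optics through a triangle-mesh canopy with a
   Monte-Carlo photon tracer.

## Measurement geometry and calibration

The instrument holds the light source fixed (beam along +Y, so the
surface-to-source direction is `L = (0, -1, 0)`) and realises all angles
mechanically: the leaf-holder scale sets the leaf inclination
(`theta_leaf = 95 - holder_scale`, the 95-degree offset being the
perpendicular-illumination reference of the mechanics), and a detection ring
carries the collimation lens over zenith angles from -5 to 175 degrees. The
leaf normal is `N = (sin t, -cos t, 0)`.

For the viewing vector the printed instrument equation,
`(sin t_v cos p_v, -sin t_v, sin t_v sin p_v)`, is not a unit vector and
collapses to zero at `t_v = 0`, where the detector in fact sits in the beam
(coincident with `L`). We therefore default to the corrected spherical form
`(sin t_v cos p_v, -cos t_v, sin t_v sin p_v)`, which is unit length and has
the right limit; the printed form remains available via
`v_form = "as_printed"` for comparison, normalized and erroring at
`t_v = 0`. No tabulated worked example exists to confirm the correction
against, so both forms are kept user-selectable.

Angles are degrees at every user-facing boundary and radians internally.
Frames in which the source or detector lies in or behind the leaf plane
(`L.N <= 0` or `N.V <= 0`, with a 1e-8 floor against floating-point
grazing artifacts) are flagged degenerate and *excluded* from fitting rather
than clamped — a clamped grazing frame would contribute an unbounded
`1/cos` factor.

Calibration needs no absolute radiometry: with the reference whiteboard an
ideal Lambertian surface (bidirectional reflectance `1/pi`), the sample
reflectance is the flux ratio `f_samp = phi_sample / (pi * phi_reference)`
measured under identical geometry; solid angle and incident flux cancel. The
whiteboard itself is validated by regressing reflected intensity on
`cos(theta_v)` — `lambertian_check()` reports the R^2 of that line.

## The Cook–Torrance model

The fitted model is

`f = F(n, theta_h) D(alpha, sigma) G / (c (L.N)(N.V)) + k / pi`

with the unpolarized Fresnel factor `F`, the Beckmann slope distribution
`D(alpha, sigma) = exp(-(tan(alpha)/sigma)^2) / (sigma^2 cos^4 alpha)`, and
the usual shadowing/masking term
`G = min(1, 2(V.N)(N.H)/(V.H), 2(L.N)(N.H)/(V.H))`. Three parameters carry
the biology:

* `sigma` (0–1): RMS microfacet slope; larger values spread the specular
  lobe.
* `k` (0–1): weight of the Lambertian component `k/pi`.
* `n` (1–5): refractive index of the cuticle interface; at `n = 1` the
  Fresnel factor vanishes and the model is exactly Lambertian. Cuticle
  absorption is neglected (the cuticle is a low-absorption medium), so no
  absorption term appears inside `F`.

Two implementation choices deserve emphasis. First, the specular
normalization constant prints ambiguously ("2π2") in the source material
for this model family; we default to `c = 2 pi^2` (`"as_printed"`) and
expose `"pi"` and `"four"` so fits can be rerun under the classical
normalizations — fitted parameters are convention-dependent and the tag is
stored in every fit. Second, the Beckmann form above is implemented exactly
as written, without the `1/pi` prefactor common in rendering literature;
the two differ only by a constant that the fitted parameters absorb, but
the difference matters when comparing parameter values across software.

## Fitting

Per wavelength and surface, parameters are estimated by minimizing the
unweighted SSE over all non-degenerate geometries pooled across incidence
angles (no weighting scheme is assumed). Defaults: initial point
`(0.5, 0.5, 3)` and box bounds `(0.01, 0.01, 1.1)–(0.99, 0.99, 5)`, a
numerically stable interior of the physical ranges.

`fit_brdf()` offers two solvers:

* **Bounded least squares** — a PORT quasi-Newton descent on the SSE
  followed by a Levenberg–Marquardt polish. The two-stage scheme is
  deliberate: plain LM projected onto the box frequently terminates on the
  `n = 5` or `k = 0.99` face in a constrained local minimum, while the
  descent stage reaches the global basin from the fixed initial point in
  every test we run. Both stages are deterministic; no multi-start is used.
* **Adaptive grid search** — a two-layer grid (steps 1e-2 then 1e-4). The
  coarse layer sweeps `(sigma, n)` *jointly* over the full bounds with the
  closed-form optimal `k` at every node (`k` enters the model linearly),
  then runs cyclic per-parameter sweeps; the fine layer repeats re-centered
  joint grids within one coarse step, then per-parameter fine sweeps. The
  joint treatment of `(sigma, n)` exists because the two parameters trade
  off along a narrow diagonal valley of the SSE surface, where strictly
  per-parameter sweeps crawl and stall one coarse step short of the
  optimum. Ties break to the smaller parameter value; sweeps stop when the
  relative SSE improvement falls below 1e-12 or after `max_sweeps = 100`
  sweeps per layer (the budget a full fine-layer convergence needs on the
  reference problems). The SSE trace is recorded and is non-increasing by
  construction.

On noiseless synthetic scans both solvers recover random in-bounds truths to
within 1e-2 per parameter and agree with each other to the same tolerance.
Under 5% multiplicative flux noise, `sigma` and `k` recover with median
absolute error below 0.05, while `n` is the soft direction of the model —
the Fresnel factor varies slowly in `n`, so the same reflectance noise maps
to a median `n` error near 0.06–0.13 depending on the truth region. This is
an identifiability property of the model at this noise level, not a solver
artifact.

Goodness of fit is `R^2 = 1 - SSE/SStot` about the observed mean plus RMSE.
Note a structural consequence: for a surface that is actually Lambertian
(`n = 1` truth), the model explains only the mean, so R^2 on noisy data is
near zero *by construction* however good the fit — R^2 is a useful summary
only when the scan contains angular structure.

## Image-based roughness

`replicate_roughness()` reimplements the cross-section analysis: the ROI is
segmented by a global Otsu threshold, the largest connected component is
taken as tissue, and the per-column extremal pixel (topmost for adaxial)
forms the surface path. The roughness is `rho = l_inner / l_outer`, the
exact path length over its Gaussian-smoothed counterpart.

Decisions the original description leaves open, fixed here: the inner length
uses the 8-connected metric (axial steps 1, diagonal steps sqrt 2) — a raw
pixel count would depend on scan direction; the smoothing is a 1-D Gaussian
on the row profile (reflect padding) with default `sigma` equal to 2% of the
ROI width; the outer length is the polyline length of the smoothed profile.
Because smoothing shortens any profile, `rho >= 1` up to discretization.
Five ROIs with randomized width (30–80% of the image width) and position are
analysed per image under a seeded generator, mitigating placement bias while
staying reproducible. Against the analytic arc-length ratio of sinusoidal
fixtures the measured `rho` agrees within 5% across amplitudes 4–8 px and
periods 40–80 px; the residual bias is the familiar metrication error of
8-connected paths (up to +8% at slopes near 0.5) partially cancelled by the
amplitude the smoothing kernel leaves in the outer profile.

## Trait features and the stacking ensemble

Pigments follow the standard spectrophotometric formulas
(`Chl.a = 12.72 A663 - 2.59 A645`, `Chl.b = 22.88 A645 - 4.67 A663`,
`Car = (1000 A470 - 3.27 Chl.a - 104 Chl.b)/229`); negative outputs are
flagged, never clamped, since the downstream model standardizes features
anyway and clamping would distort them silently. Specific leaf weight is dry
mass over area. The nine predictors are thickness, SLW, the three pigments,
total chlorophyll, the chlorophyll a/b ratio, image roughness `rho`, and
wavelength.

`train_el()` predicts one BRDF parameter at a time (separate models per
parameter): an 8:2 train/test split; z-scoring fitted on the training rows
only; recursive feature elimination down to 5 features using random-forest
importance; per-base-learner grid search (SVR cost in {0.1, 1, 10}; forest
size in {100, 300}; boosting depth in {2, 3} — small published defaults,
since no grids are prescribed) minimizing 10-fold CV MSE; and a linear
meta-learner trained on *out-of-fold* base predictions, the standard-safe
stacking construction that keeps the meta-learner from seeing any base
learner's in-sample fit. Everything is seeded and the test rows provably
never influence the fitted pipeline (scrambling test labels changes no
fitted coefficient). On the 270-row synthetic benchmark the stacked model
reaches held-out R^2 near 0.89 for `sigma` against a noise ceiling of about
0.92, and is never more than 10% worse in MSE than its best base learner.

## The synthetic-data generators

The generators define the study conditions and are first-class, tested code:

* `synth_brdf_scan()` forward-evaluates the model on the instrument grid
  (incidence 0, 30, 45, 55 degrees; ring every 5 degrees over -5..175),
  inverts the calibration to flux pairs (reference flux proportional to
  `cos(N.V)`), and applies multiplicative Gaussian noise (default sd 0.05)
  to both fluxes — spectrometer-like shot behavior that keeps reflectance
  non-negative, unlike an additive floor.
* `synth_whiteboard_scan()`: cosine-law intensities at 19 angles in
  [0, 90), default noise sd 0.01.
* `synth_section_image()`: a tissue band under a sinusoidal boundary with
  speckle noise, returning the analytic arc-length roughness of the
  generating curve as its own oracle.
* `synth_trait_dataset()` (default n = 270): realistic trait ranges
  (thickness ~0.25 mm, SLW tens of g m^-2^ and correlated with thickness,
  absorbances in spectrophotometer range) and targets built from the
  observed correlation structure — `sigma` linear in `rho`, `k` increasing
  with wavelength, `n` decreasing with thickness and SLW — plus Gaussian
  noise (default sd 0.03, chosen so the best achievable R^2 is in the low
  0.9s, matching the reported performance band on real data). Targets are
  clipped to the physical bounds.
* `synth_canopy()`: randomly placed tilted triangular leaves in
  equal-thickness layers of a 1 m box, with per-layer optics.

What these fixtures do *not* emulate: instrument-specific noise spectra,
chromatic aberration, vein or tip artifacts in sections, and the
species-by-layer covariance of real trait tables. Passing tests therefore
demonstrate correctness of the algorithms under controlled conditions, not
field performance.

## Canopy photon tracing

`trace_photons()` is a minimal single-band Monte-Carlo tracer. Photons are
emitted uniformly over the mesh's horizontal extent just above its top and
intersected with facets by the Möller–Trumbore test. At a hit the fate is
reflect / transmit / absorb with probabilities `{R(omega_i), tau, 1-R-tau}`:
the reflection probability is the directional-hemispherical reflectance of
the facet's BRDF (Gauss–Legendre product quadrature over the exit
hemisphere, interpolated from a per-optics lookup over incidence cosines;
for `n = 1` it is exactly `k`). `tau` defaults to 0.05 and is an explicit
free input — no published transmittance accompanies the parameter sets.
Reflected directions mix a cosine-weighted diffuse lobe (weight `k/R`) with
a Beckmann specular lobe sampled about the half-vector with
Fresnel-and-shadowing rejection (a bounded-iteration sampler that falls
back to the mirror direction after 200 rejections; the energy split itself
is exact via `R`, so the approximation touches only the angular shape of an
already-narrow lobe). Transmission is cosine-weighted into the far
hemisphere, matching the near-Lambertian character of leaf transmission.

Units: one photon carries `ppfd x domain_area / n_photons` of flux, and a
facet's PPFD is its accumulated flux over facet area. A facet's *scattered*
PPFD counts only photons arriving after at least one earlier surface
interaction; the direct beam is tallied separately so that scattered-light
analyses are not swamped by direct interception. The photon ledger
(absorbed + exited + terminated-at-`max_bounces` = emitted) is exact on
every run; `max_bounces` is a hard 20 with no Russian roulette.
`layer_summary()` slices the canopy into equal-thickness layers by facet
centroid, reporting area-weighted means and an intensity histogram
(default bins 0–40, 40–80, 80–150, >150 umol m^-2^ s^-1^).

The tracer reproduces the expected physics on oracles: pure-diffuse
reflectance integrates to `k` within 1e-4; reflected directions pass a
chi-square test against the cosine density; bottom-to-top scattered flux on
a two-plate configuration matches the analytic view-factor computation
within Monte-Carlo error; and raising the diffuse coefficient from 0.01 to
0.35 strictly brightens the upper canopy layers' scattered PPFD.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run at desk scale: 20 replicate
fits per parameter set, 2 x 10^4^ photons on a 120-facet canopy (6 x 10^4^
for the view-factor oracle), and one 270-row ensemble training — sizes at
which every check is stable under seed changes while the whole suite
completes in well under a minute. All randomness flows through explicit
seeds; rerunning any pipeline with the same seeds reproduces results
byte-for-byte.

## Known limitations

* `n` is weakly identified from reflectance alone at realistic noise; treat
  fitted refractive indices as having wider uncertainty than `sigma` or `k`.
* For truly Lambertian surfaces the model's specular lobe cannot vanish
  (the `n >= 1.1` stability bound), leaving a small systematic floor —
  visible only when the diffuse signal is itself tiny.
* The specular direction sampler is an importance sampler with bounded
  rejection, exact in energy but approximate in lobe shape.
* Single-band tracing only; no sky model, no spectral coupling, no
  polarization, and no multi-layer plate optics — `n` parameterizes the
  interface directly.
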