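---
title: "Modelling and measuring SMC deformation after short-duration heating dilatation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring SMC deformation after short-duration heating dilatation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smcdeform)
```

## The problem

Short-duration heating balloon dilatation widens a stenosed artery by
briefly (about 15 s) heating the vessel wall through the balloon while
applying low pressure. Collagen denatures thermally from about 60 °C,
transiently softening the wall, so the lumen can be enlarged *without
plastic deformation* — the wall stretches as a continuum instead of
tearing. A measurable consequence is that the smooth muscle cells (SMCs) of
the media, which lie nearly circumferentially, are fixed in a stretched
state: their nuclei become more elongated. This package implements the full
quantitative chain needed to model and measure that effect:

1. a balloon temperature protocol generator;
2. a 1-D transient conduction model of the balloon film and wall with an
   apparent (temperature-band) heat capacity, giving the depth of wall
   heated above the 60 °C threshold;
3. area-conserving dilation mechanics of the wall annulus;
4. a synthetic histology generator with exact ground truth;
5. nuclei morphometry by second-order image moments;
6. the rate statistics: SMC deformation rate, arterial dilatation rates,
   vessel-wall transformation rate, media area-conservation checks, and an
   end-to-end experiment driver.

## Balloon temperature protocol

The balloon fluid temperature ramps from body temperature (37 °C) to its
peak `t_peak` following a saturating exponential with time constant
`heating_time / 3`, normalised so the maximum is reached exactly at
laser-off — the balloon is hottest just before the laser stops. The ramp
shape is a modelling choice: the documented behaviour constrains only the
peak location and the cooling bound, and a saturating rise reproduces both
without overshoot.

After laser-off the balloon is still flushed by unheated contrast media, so
its temperature decays *below* body temperature. We model this as a single
exponential toward a coolant temperature (default 25 °C, a room-temperature
irrigate) with time constant 18 s. With these defaults the balloon is below
37 °C within 60 s of laser-off for every peak up to 90 °C, which the
`heating_protocol()` constructor enforces as an invariant. A decay toward
37 °C itself could never satisfy that bound — an exponential never crosses
its asymptote — which is why the coolant asymptote is a separate, exposed
parameter. A protocol whose peak equals the baseline represents "no
procedure" and evaluates to a constant 37 °C.

## Conduction model and the heated depth

`solve_heat()` integrates the 1-D heat equation through the layer stack
(balloon film, then tissue) on a uniform grid, with the balloon history as
a Dirichlet condition on the film's inner surface and a fixed 37 °C bath at
the outer surface (an insulated option exists for sensitivity analysis).
Material properties: wall density 1.0·10⁻³ g/mm³ and conductivity
4.2·10⁻⁴ W/(mm·°C); film 1.0·10⁻³ and 2.4·10⁻⁴; film specific heat
2.0 J/(g·°C). The wall's specific heat is piecewise constant in
temperature — 5.0 below 40 °C, then 5.6, 6.7, 8.2, 11.0 and 12.0 up to
90 °C — the *apparent heat capacity* device: the extra heat absorbed per
degree in the hotter bands stands in for the latent heat of collagen
denaturation. Temperatures outside the table raise an error naming the band
gap rather than extrapolating.

Numerical choices:

* **Scheme.** Backward Euler (unconditionally stable), with the node heat
  capacity re-evaluated each step from the current temperature's band
  (explicit lagging of the nonlinearity). A forward-Euler variant is kept
  as a cross-check; it refuses any time step above its stability bound and
  reports the admissible maximum.
* **Mesh.** `dr` must divide every layer thickness so interfaces fall on
  nodes; conductances are per cell, capacities per node from the adjacent
  half-cells. Defaults `dr = 0.0025` mm, `dt = 0.025` s; halving both moves
  the heated depth by ~10⁻⁴ mm, far inside the 0.005 mm convergence
  tolerance we test.
* **Geometry.** Planar by default — the wall is ~0.5 mm thin at a ~1.5 mm
  lumen, and the tests confirm the cylindrical option (also provided)
  differs only marginally at this curvature.
* **Verification.** The solver is checked against the closed-form
  complementary-error-function solution for a sudden boundary step on a
  constant-property slab (agreement within 0.2 °C), against the linear
  steady state, and against the discrete maximum principle.

`heated_depth()` reports the largest depth into the wall (film excluded)
whose *peak-over-time* temperature reaches the threshold (default 60 °C),
interpolating linearly between nodes. Peak-over-time is chosen over any
instantaneous definition because it is monotone and well defined for
transient protocols.

**Calibration.** The film thickness is not documented and the conduction
domain must end somewhere: these are the model's two calibration
parameters. A domain that stops at the media's outer surface (0.54 mm)
with a 37 °C bath cannot produce a 0.42 mm heated depth at an 85 °C peak —
the steady profile caps near 0.24 mm — so the calibrated domain extends the
tissue beyond the media (adventitia and surrounding tissue, assigned the
same thermal properties) out to the bath boundary. The shipped values,
film 0.0775 mm and total tissue 0.9725 mm, were fixed once by a grid
search against the two reference heated depths (0.05 mm at a 65 °C peak,
0.42 mm at 85 °C, 15 s heating) and are versioned in
`calibrated_thermal_setup()`. They are calibration constants of the model,
not blind predictions; the monotone growth of heated depth with balloon
temperature and heating time is a genuine prediction and is tested.

## Area-conserving dilation mechanics

The wall cross-section is an annulus with inner radius $r$ and thickness
$t$; the artery is held at a fixed 1.2-fold axial stretch before, during
and after dilation, so all deformation is in-plane. Dilation without
plastic deformation conserves wall volume, hence in-plane area:

$$t' = \sqrt{r'^2 + 2rt + t^2} - r', \qquad
  r_{\text{after}}(r_b) = \sqrt{r'^2 + r_b^2 - r_i^2}.$$

The local stretches are $\lambda_\theta = r_{\text{after}}/r_b$
(circumferential) and $\lambda_r = \mathrm{d}r_{\text{after}}/\mathrm{d}r_b
= 1/\lambda_\theta$, so a circumferentially oriented nucleus has its aspect
ratio multiplied by exactly $\lambda_\theta^2$. A nucleus tilted by $\psi$
radians from circumferential gets a smaller multiplier; numerically the
deviation is bounded below by the factor $(1 - 2.5\,\psi^2)$ over the
realistic range ($\lambda_\theta \le 1.45$, aspect 1.5–4, $|\psi| \le
0.35$), which the tests verify.

The **transformation rate** — (inner diameter / wall thickness) after,
divided by the same before — uses the *inner* diameter, matching the
ex-vivo dilatation-rate convention; the bulk measure is deliberately the
same quantity a pathologist could read off a section. Note that the
transformation rate and the mean nuclear aspect multiplier are *not* equal
pointwise: for the default geometry and a dilatation rate of 1.2 the
mid-wall $\lambda_\theta^2$ is already ~8% below the transformation rate,
and the gap grows with dilation. What holds — and what we test — is the
exact closed form for the cohort-mean multiplier,
$1 + 2(r_i'^2 - r_i^2)\ln(r_o/r_i)/(r_o^2 - r_i^2)$ for area-uniform
nuclei, and the tight monotone association between deformation and
transformation rates (Pearson r ≥ 0.99 across a cohort), which is the
relationship the measurement method's validity rests on.

## Synthetic histology generator

`generate_cohort()` produces paired before/after phantoms with known ground
truth. Defaults encode the study conditions: porcine carotid geometry
(inner diameter 1.46 mm, media thickness 0.54 mm), 6 specimens per
condition, ex-vivo balloon peaks 60–75 °C (4 × 6 = 24 specimens), axial
stretch 1.2. Values the source material does not state are explicit,
configurable assumptions:

* nuclei per specimen: 100 (how many were measured per section is
  undocumented);
* baseline nuclear aspect ratio: lognormal, mean 2.5, sd 0.4 — a typical
  elongation for medial SMC nuclei in section;
* nuclear short axis 0.008 mm; orientation jitter sd 0.1 rad about the
  local circumferential direction (SMCs run low-angle spirally);
* measurement noise: multiplicative lognormal with CV 0.02 per axis,
  applied at render time, representing focus/staining/outlining
  variability;
* chronic remodelling: a relaxation factor defaulting to 0 (the stretched
  state persists into the chronic phase).

Nuclei are placed area-uniformly in the annulus with a simple
overlap-rejection rule, and each candidate must fit inside the annulus in
*both* states — after dilation, radial gaps compress while long axes grow,
so the after-state check is the binding one near the lumen. The after
nuclei are derived from the before nuclei through the exact ellipse
transform under the local stretch tensor, never re-sampled; the
conventional-balloon arm keeps nuclear shape identical (plastic dilation
fragments the wall instead of stretching it). The dose–response link from
balloon temperature to target dilatation rate is injectable; the default,
`1 + (0.5/0.42) · heated_depth(T)`, ties dilation to the softened depth and
spans rates 1.0–1.5 over 60–85 °C. (At a 60 °C peak no wall tissue crosses
the threshold, so the heated depth — and the dilation beyond rate 1 — is
zero.)

Rendering rasterises the phantom as a grayscale section — white background
(1.0), media 0.8, nuclei 0.15 — at a pixel size chosen so the smallest
nuclear short axis spans 8 px (capped at 0.001 mm/px); explicit pixel sizes
letting a short axis fall under 6 px are refused rather than silently
biasing the moments. What the phantoms do *not* emulate: staining colour
and artefacts, touching-nuclei clumps, sectioning obliquity, 3-D tissue
context, and any live-tissue mechanics (the conventional arm's pressure
dependence is out of scope). Passing tests therefore demonstrate the
correctness of the measurement chain, not the biology of real sections.

## Morphometry

`segment_nuclei()` thresholds dark nuclei and labels connected components
(area filter, border-exclusion policy). The automatic threshold is a
two-stage Otsu: one pass over the whole image, then — if the sub-threshold
pixels still show contrast (tissue plus nuclei) — a second pass within
them; a contrast-free sub-threshold class is accepted as nuclei only if it
is darker than half the background. A fixed threshold is exposed for user
images. `fit_ellipse()` uses the equivalent-ellipse convention — full axis
$= 4\sqrt{\lambda}$ for each eigenvalue of the pixel covariance — which is
deterministic, oracle-checkable, and unbiased for true ellipses, replacing
the manual axis measurements of the original workflow. The deformation
rate is the ratio of mean aspect ratios (after/before): before and after
specimens are different sections, so nuclei are pooled per state, and a
seeded nonparametric bootstrap over nuclei gives the uncertainty. No
outlier rejection is applied by default.

## Statistics and the experiment driver

`dilatation_rate_ex_vivo()` is the inner-diameter ratio;
`dilatation_rate_in_vivo()` is the square root of the dilated-to-control
luminal area ratio (the two agree on circles). `area_ratio()` measures
media area from the images, pixel-size corrected. Group comparisons use
the classical Student t test (two-sided, pooled variance; Welch by flag)
and raw p values are reported without multiple-testing correction,
mirroring the original analysis. The correlation between deformation and
transformation rates is computed across specimens (computing it across
condition means is the plausible alternative; across specimens is the
stricter reading and is what we implement).

`run_experiment()` chains everything — cohort, rendering, morphometry,
rates, statistics — and writes `rates.csv`, `report.json`, `report.md` and
the ground truth, with a provenance block (seed, config hash, versions)
and byte-identical output for a fixed seed.

## Problem sizes and runtimes

The shipped analyses are sized for a desk machine: conduction solves use
~420 nodes × ~1 800 steps (about a second each); the correlation cohort is
20 specimens × 100 nuclei with images up to ~6 000 px square; the
area-conservation cohort is 24 specimens. The full test suite runs in a
few minutes on one core.

## Known limitations

* The heated-depth endpoints are calibrated, not predicted; only their
  monotone structure is predictive.
* The dose–response link is a configurable stand-in — no constitutive
  (Young's modulus) model of heated tissue is included, so conventional-arm
  dilatation rates and in-vivo chronic biology are out of scope.
* The transformation rate approximates the mean nuclear multiplier only
  loosely (see above); conclusions should rest on the correlation, not on
  pointwise equality.
* Morphometry assumes non-touching, ellipse-like nuclei; watershed
  splitting and stain deconvolution are not implemented.

```{r example, eval = FALSE}
# a minimal end-to-end run (about a minute)
cfg <- experiment_config(t_balloon_levels = c(65, 75, 85),
                         n_specimens_per_condition = 2,
                         nuclei_per_specimen = 50, rng_seed = 1)
report <- run_experiment(cfg)
print(report)
```
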