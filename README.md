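# smcdeform

Modelling and measurement of smooth-muscle-cell (SMC) deformation after
**short-duration heating balloon dilatation** of arteries.

Short-duration thermal angioplasty heats the vessel wall for ~15 s through
the balloon while applying low pressure. Collagen denatures thermally from
about 60 °C, transiently softening the wall, so the lumen is enlarged
*without plastic deformation*: the wall stretches as a continuum, and the
near-circumferential SMCs of the media are fixed in a stretched state. The
histological readout is the elongation of SMC nuclei. This package is for
researchers who want to model that mechanism and quantify it from (real or
synthetic) histology sections.

## What it computes

* **Thermal dose.** A 1-D transient conduction solver for the balloon film
  + arterial wall with an apparent (temperature-band) heat capacity — the
  wall's specific heat steps from 5.0 to 12.0 J/(g·°C) across 40–90 °C,
  folding collagen-denaturation latent heat into the conduction equation —
  and the **heated depth**: the wall depth whose peak temperature exceeds
  the 60 °C threshold.
* **Mechanics.** Area-conserving dilation of the wall annulus at fixed
  axial stretch: after-thickness `t' = sqrt(r'^2 + 2rt + t^2) − r'`, local
  stretches `λ_θ · λ_r = 1`, and the **transformation rate**
  `(D'/t')/(D/t)`.
* **Morphometry.** Nuclei segmentation and equivalent-ellipse fitting by
  second-order image moments; the **deformation rate** = (mean nuclear
  long/short ratio after) / (before), with bootstrap CIs.
* **Statistics.** Arterial dilatation rates (ex-vivo diameter and in-vivo
  √area conventions), media area-conservation checks from images, Pearson
  correlation, Student t tests, and an end-to-end reproducible synthetic
  experiment driver with known ground truth.

## Worked example

```r
library(smcdeform)

# dilate the porcine carotid geometry to a 2.0 mm lumen, conserving area
geom <- vessel_geometry(inner_diameter = 1.46, wall_thickness = 0.54)
map  <- dilate_area_conserving(geom, 2.0)
map
#> Area-conserving deformation map: inner diameter 1.460 -> 2.000 mm, thickness 0.540 -> 0.442 mm
transformation_rate(map$before, map$after)
#> [1] 1.672754
local_stretch(map, 1.0)          # mid-wall circumferential / radial stretch
#> $lambda_theta 1.211239   $lambda_r 0.8256009

# heated depth under the calibrated conduction model, 15 s heating
sapply(c(65, 75, 85), heated_depth_at)
#> [1] 0.05018433 0.28238730 0.42125933

# one synthetic specimen, measured end to end
cfg <- cohort_config(nuclei_per_specimen = 100, rng_seed = 42)
ph  <- generate_phantom(cfg, dilatation_rate = 1.4, seed = 42)
before <- measure_nuclei(render_histology_image(ph, "before"))
after  <- measure_nuclei(render_histology_image(ph, "after"))
deformation_rate(after, before)$rate
#> [1] 1.497
```

Reading the numbers: dilating the lumen from 1.46 to 2.0 mm thins the wall
to 0.442 mm (area conserved), a transformation rate of 1.67; a mid-wall
material point stretches 1.21× circumferentially and compresses to 0.83×
radially, so a circumferential nucleus elongates by 1.21² ≈ 1.47 — which is
what the image-based deformation rate recovers (1.497, 95% bootstrap CI
1.43–1.57). The heated depth grows monotonically with balloon peak
temperature, 0.05 → 0.42 mm over 65–85 °C.

A full synthetic experiment (cohort → images → morphometry → statistics →
report files):

```r
report <- run_experiment(experiment_config(rng_seed = 1), out_dir = "results")
```

or from a shell, `Rscript inst/scripts/run-experiment.R --config exp.yaml
--out results/`. See the methods vignette
(`vignettes/smc-deformation-methods.Rmd`) for the model assumptions,
parameter choices and limitations.

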