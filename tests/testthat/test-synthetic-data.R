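test_that("cohorts are bit-identical for a fixed seed", {
  cfg <- small_cohort_config(target_dilatation_rates = c(1.15, 1.4),
                             rng_seed = 7)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  # and renders are reproducible too
  i1 <- render_histology_image(c1[[1]], "after")
  i2 <- render_histology_image(c2[[1]], "after")
  expect_identical(i1$image, i2$image)
})

test_that("default cohort uses the porcine carotid geometry", {
  cfg <- cohort_config(target_dilatation_rates = 1.2, nuclei_per_specimen = 5,
                       rng_seed = 2)
  ph <- generate_cohort(cfg)[[1]]
  expect_equal(2 * ph$geometry_before$inner_radius, 1.46)
  expect_equal(ph$geometry_before$wall_thickness, 0.54)
  expect_equal(ph$geometry_before$axial_stretch, 1.2)
})

test_that("identity link leaves every nucleus unchanged", {
  cfg <- small_cohort_config(t_balloon_levels = c(60, 75),
                             n_specimens_per_condition = 1)
  cohort <- generate_cohort(cfg, link = function(tb) rep(1, length(tb)))
  for (ph in cohort) {
    expect_equal(ph$nuclei_after$long_axis_mm, ph$nuclei_before$long_axis_mm)
    expect_equal(ph$nuclei_after$short_axis_mm, ph$nuclei_before$short_axis_mm)
    expect_equal(ph$nuclei_after$centroid_r_mm, ph$nuclei_before$centroid_r_mm)
  }
  expect_error(generate_cohort(cfg, link = function(tb) rep(0.9, length(tb))),
               class = "smcdeform_validation_error")
})

test_that("conventional-arm phantoms keep nuclear shape exactly", {
  cfg <- small_cohort_config(arm = "conventional",
                             t_balloon_levels = 1.0,
                             n_specimens_per_condition = 2)
  cohort <- generate_cohort(cfg)
  for (ph in cohort) {
    expect_identical(ph$nuclei_after, ph$nuclei_before)
    expect_null(ph$map)
  }
})

test_that("ground-truth aspect multiplier equals lambda_theta^2, bounded under jitter", {
  # without orientation jitter the identity is exact
  cfg0 <- small_cohort_config(orientation_jitter_sd = 0)
  ph0 <- generate_phantom(cfg0, dilatation_rate = 1.35, seed = 9)
  lt2 <- local_stretch(ph0$map, ph0$nuclei_before$centroid_r_mm)$lambda_theta^2
  mult0 <- (ph0$nuclei_after$long_axis_mm / ph0$nuclei_after$short_axis_mm) /
    (ph0$nuclei_before$long_axis_mm / ph0$nuclei_before$short_axis_mm)
  expect_equal(mult0, lt2, tolerance = 1e-9)
  # with jitter psi the multiplier stays within [lt^2 (1 - 2.5 psi^2), lt^2]
  cfg1 <- small_cohort_config(orientation_jitter_sd = 0.1)
  ph1 <- generate_phantom(cfg1, dilatation_rate = 1.35, seed = 9)
  lt2 <- local_stretch(ph1$map, ph1$nuclei_before$centroid_r_mm)$lambda_theta^2
  mult1 <- (ph1$nuclei_after$long_axis_mm / ph1$nuclei_after$short_axis_mm) /
    (ph1$nuclei_before$long_axis_mm / ph1$nuclei_before$short_axis_mm)
  psi <- ph1$nuclei_before$orientation_rad
  expect_true(all(mult1 <= lt2 * (1 + 1e-9)))
  expect_true(all(mult1 >= lt2 * (1 - 2.5 * psi^2) - 1e-9))
})

test_that("cohort mean ground-truth multiplier matches the closed form", {
  cfg <- cohort_config(geometry = exvivo_geometry(), nuclei_per_specimen = 400,
                       orientation_jitter_sd = 0, rng_seed = 13,
                       target_dilatation_rates = 1.3)
  ph <- generate_cohort(cfg)[[1]]
  mult <- (ph$nuclei_after$long_axis_mm / ph$nuclei_after$short_axis_mm) /
    (ph$nuclei_before$long_axis_mm / ph$nuclei_before$short_axis_mm)
  expected <- mean_aspect_multiplier(ph$map)
  # sampling error of an area-uniform draw of 400 nuclei
  expect_lt(abs(mean(mult) - expected) / expected, 0.01)
})

test_that("nuclei lie inside the media annulus in both states", {
  cfg <- small_cohort_config()
  ph <- generate_phantom(cfg, dilatation_rate = 1.4, seed = 21)
  for (state in c("before", "after")) {
    nuc <- if (state == "before") ph$nuclei_before else ph$nuclei_after
    geom <- if (state == "before") ph$geometry_before else ph$geometry_after
    expect_true(all(nuc$centroid_r_mm - nuc$long_axis_mm / 2 >
                      geom$inner_radius - 1e-9))
    expect_true(all(nuc$centroid_r_mm + nuc$long_axis_mm / 2 <
                      outer_radius(geom) + 1e-9))
  }
})

test_that("area conservation holds by construction for the heating arm", {
  cfg <- small_cohort_config()
  ph <- generate_phantom(cfg, dilatation_rate = 1.5, seed = 3)
  expect_lt(abs(annulus_area(ph$geometry_after) /
                  annulus_area(ph$geometry_before) - 1), 1e-12)
})

test_that("rendering a phantom without nuclei gives a blank annulus", {
  cfg <- small_cohort_config(nuclei_per_specimen = 1)
  ph <- generate_phantom(cfg, dilatation_rate = 1, seed = 1)
  ph$nuclei_before <- ph$nuclei_before[0, ]
  img <- render_histology_image(ph, "before")
  expect_setequal(unique(as.vector(img$image)), c(1, 0.8))
  # annulus area correct to rasterisation accuracy
  expect_lt(abs(sum(img$image == 0.8) * img$pixel_size^2 /
                  annulus_area(ph$geometry_before) - 1), 0.005)
})

test_that("a rasterised nucleus covers the expected pixel area", {
  cfg <- small_cohort_config(nuclei_per_specimen = 1,
                             measurement_noise_cv = 0)
  ph <- generate_phantom(cfg, dilatation_rate = 1, seed = 5)
  ph$nuclei_before$long_axis_mm <- 0.020
  ph$nuclei_before$short_axis_mm <- 0.008
  img <- render_histology_image(ph, "before", pixel_size = 0.001)
  area_px <- sum(img$image == 0.15)
  expect_lt(abs(area_px - pi * 10 * 4) / (pi * 10 * 4), 0.05)
  # halved pixel size: ~4x the pixel area
  img2 <- render_histology_image(ph, "before", pixel_size = 0.0005)
  expect_lt(abs(sum(img2$image == 0.15) / area_px - 4), 0.2)
})

test_that("too-coarse rendering resolution is refused", {
  cfg <- small_cohort_config(nuclei_per_specimen = 3)
  ph <- generate_phantom(cfg, dilatation_rate = 1, seed = 2)
  expect_error(render_histology_image(ph, "before", pixel_size = 0.002),
               class = "smcdeform_resolution_error")
})

test_that("image files round-trip with their pixel-size sidecar", {
  cfg <- small_cohort_config(nuclei_per_specimen = 5)
  ph <- generate_phantom(cfg, dilatation_rate = 1.2, seed = 2)
  img <- render_histology_image(ph, "before")
  for (ext in c("tif", "png")) {
    path <- file.path(tempdir(), paste0("b.", ext))
    write_histology_image(img, path)
    back <- read_histology_image(path)
    expect_equal(back$pixel_size, img$pixel_size)
    expect_lt(max(abs(back$image - img$image)), 1 / 255)
    unlink(c(path, paste0(path, ".json")))
  }
})

test_that("ground-truth export has the documented columns", {
  cfg <- small_cohort_config(nuclei_per_specimen = 4,
                             target_dilatation_rates = c(1.1, 1.2))
  cohort <- generate_cohort(cfg)
  gt <- cohort_ground_truth(cohort)
  expect_named(gt, c("specimen_id", "state", "nucleus_id", "centroid_r_mm",
                     "centroid_theta_rad", "long_axis_mm", "short_axis_mm",
                     "orientation_rad"))
  expect_equal(nrow(gt), 2 * 2 * 4)
  expect_true(all(gt$long_axis_mm >= gt$short_axis_mm))
  path <- file.path(tempdir(), "gt.csv")
  write_ground_truth(cohort, path)
  expect_equal(nrow(utils::read.csv(path)), nrow(gt))
  unlink(path)
})
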