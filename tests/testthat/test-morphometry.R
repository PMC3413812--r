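test_that("blank images yield zero regions with a warning", {
  expect_warning(seg <- segment_nuclei(matrix(1, 60, 60), pixel_size = 0.001),
                 "no nuclei")
  expect_equal(seg$n, 0L)
  expect_equal(nrow(measure_nuclei(seg)), 0L)
  # blank annulus (tissue but no nuclei) is also empty
  cfg <- small_cohort_config(nuclei_per_specimen = 1)
  ph <- generate_phantom(cfg, dilatation_rate = 1, seed = 1)
  ph$nuclei_before <- ph$nuclei_before[0, ]
  img <- render_histology_image(ph, "before")
  expect_warning(seg2 <- segment_nuclei(img), "no nuclei")
  expect_equal(seg2$n, 0L)
})

test_that("segmentation recovers exactly the generated nucleus count", {
  cfg <- small_cohort_config(nuclei_per_specimen = 50)
  ph <- generate_phantom(cfg, dilatation_rate = 1.2, seed = 31)
  img <- render_histology_image(ph, "before")
  seg <- segment_nuclei(img)
  expect_equal(seg$n, 50L)
  # a min_area above the largest nucleus filters everything out
  expect_warning(
    seg0 <- segment_nuclei(img, params = segmentation_params(min_area = 1e6,
                                                             max_area = 1e7)),
    "no nuclei")
  expect_equal(seg0$n, 0L)
  # fixed threshold gives the same result on this contrast
  seg_f <- segment_nuclei(img, params = segmentation_params("fixed",
                                                            threshold = 0.5))
  expect_equal(seg_f$n, 50L)
})

test_that("a rasterised disk has aspect ratio 1", {
  img <- raster_ellipse(41, 21, 21, 15, 15, 0)
  m <- measure_nuclei(img, pixel_size = 0.001)
  expect_equal(nrow(m), 1L)
  expect_lt(abs(m$aspect_ratio - 1), 0.03)
})

test_that("moment fitting recovers axes and orientation of rotated ellipses", {
  # sub-pixel centre: a generic placement, as in real images
  for (phi in seq(0, pi * 11 / 12, length.out = 12)) {
    img <- raster_ellipse(95, 47.3, 47.6, 20, 8, phi)
    m <- measure_nuclei(img, pixel_size = 0.001)
    expect_equal(nrow(m), 1L)
    expect_lt(abs(m$aspect_ratio - 2.5), 0.05)
    d_ang <- abs(m$orientation_rad - phi) %% pi
    expect_lt(min(d_ang, pi - d_ang), 0.05)
  }
})

test_that("aspect ratio is invariant to scale and near-invariant to rotation", {
  m1 <- measure_nuclei(raster_ellipse(51, 26, 26, 10, 4, 0.4),
                       pixel_size = 0.001)
  m2 <- measure_nuclei(raster_ellipse(101, 51, 51, 20, 8, 0.4),
                       pixel_size = 0.0005)
  expect_lt(abs(m1$aspect_ratio / m2$aspect_ratio - 1), 0.02)
  expect_equal(m1$long_axis_mm, m2$long_axis_mm, tolerance = 0.04)
  ratios <- vapply(seq(0, pi, length.out = 13)[-13], function(phi) {
    measure_nuclei(raster_ellipse(141, 70.3, 70.6, 30, 12, phi),
                   pixel_size = 0.001)$aspect_ratio
  }, 0)
  expect_lt(diff(range(ratios)) / mean(ratios), 0.02)
})

test_that("moment axes agree with the brute-force pixel-moment oracle", {
  cfg <- small_cohort_config(nuclei_per_specimen = 20)
  ph <- generate_phantom(cfg, dilatation_rate = 1.3, seed = 17)
  img <- render_histology_image(ph, "after")
  seg <- segment_nuclei(img)
  pos <- which(seg$labels > 0L)
  ids <- seg$labels[pos]
  rc <- arrayInd(pos, dim(seg$labels))
  m <- measure_nuclei(seg)
  for (k in seq_len(seg$n)) {
    coords <- rc[ids == k, , drop = FALSE]
    fit <- fit_ellipse(coords, seg$pixel_size)
    oracle <- oracle_ellipse_axes(coords, seg$pixel_size)
    expect_lt(abs(fit$long_axis_mm / oracle$long - 1), 1e-9)
    expect_lt(abs(fit$short_axis_mm / oracle$short - 1), 1e-9)
    row <- m[m$label == k, ]
    expect_equal(row$long_axis_mm, fit$long_axis_mm)
  }
})

test_that("degenerate and undersized regions are rejected", {
  expect_error(fit_ellipse(cbind(1:5, 1:5), 0.001), "at least 6")
  expect_error(fit_ellipse(cbind(rep(3, 10), 1:10), 0.001),
               class = "smcdeform_degenerate_error")
})

test_that("specimen summaries follow their definition", {
  s1 <- summarize_specimen(2.0)
  expect_equal(s1$mean_aspect, 2.0)
  expect_equal(s1$sd_aspect, 0)
  expect_equal(s1$n_nuclei, 1L)
  s2 <- summarize_specimen(c(2, 3))
  expect_equal(s2$mean_aspect, 2.5)
  expect_error(summarize_specimen(numeric(0)),
               class = "smcdeform_validation_error")
  # large synthetic specimen: measured mean within 2 sd/sqrt(n) of ground truth
  cfg <- small_cohort_config(nuclei_per_specimen = 60)
  ph <- generate_phantom(cfg, dilatation_rate = 1, seed = 41)
  img <- render_histology_image(ph, "before")
  s <- summarize_specimen(measure_nuclei(img))
  truth <- mean(ph$nuclei_before$long_axis_mm / ph$nuclei_before$short_axis_mm)
  expect_lt(abs(s$mean_aspect - truth),
            2 * s$sd_aspect / sqrt(s$n_nuclei) + 0.03)
})

test_that("deformation rate follows its definition and bootstraps sensibly", {
  s <- summarize_specimen(c(2, 3))
  expect_equal(deformation_rate(s, s)$rate, 1.0)
  expect_equal(deformation_rate(summarize_specimen(3.0),
                                summarize_specimen(2.0))$rate, 1.5)
  a <- rep(c(2.9, 3.1), 50)
  b <- rep(c(1.9, 2.1), 50)
  dr <- deformation_rate(a, b, n_boot = 500, boot_seed = 3)
  expect_equal(dr$rate, 1.5, tolerance = 1e-12)
  expect_true(dr$ci[1] < 1.5 && 1.5 < dr$ci[2])
  expect_lt(dr$se, 0.05)
})

test_that("a mid-wall phantom's deformation rate recovers the local multiplier", {
  geom <- exvivo_geometry()
  mid <- geom$inner_radius + geom$wall_thickness / 2
  cfg <- cohort_config(geometry = geom, nuclei_per_specimen = 100,
                       nuclei_radial_range = c(mid - 0.02, mid + 0.02),
                       measurement_noise_cv = 0.02, rng_seed = 5)
  ph <- generate_phantom(cfg, dilatation_rate = 1.3, seed = 5)
  m <- local_stretch(ph$map, mid)$lambda_theta^2
  rate <- deformation_rate(measure_nuclei(render_histology_image(ph, "after")),
                           measure_nuclei(render_histology_image(ph, "before")),
                           n_boot = 0)$rate
  expect_lt(abs(rate - m) / m, 0.05)
})

test_that("conventional-arm phantoms recover a null deformation rate", {
  cfg <- cohort_config(geometry = exvivo_geometry(), arm = "conventional",
                       nuclei_per_specimen = 100, rng_seed = 19)
  ph <- generate_phantom(cfg, dilatation_rate = 1, seed = 19)
  rate <- deformation_rate(measure_nuclei(render_histology_image(ph, "after")),
                           measure_nuclei(render_histology_image(ph, "before")),
                           n_boot = 0)$rate
  expect_gte(rate, 0.95)
  expect_lte(rate, 1.05)
})
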