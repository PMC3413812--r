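test_that("constant 37 degC boundary keeps the whole field at equilibrium", {
  h <- temperature_history(heating_protocol(37), dt = 0.1)
  f <- solve_heat(h, list(balloon_film_layer(0.05), arterial_wall_layer(0.54)),
                  thermal_config(dr = 0.005, dt = 0.1), duration = 5)
  expect_true(all(abs(f$temps - 37) < 1e-9))
})

test_that("solver matches the semi-infinite erfc step-response oracle", {
  # constant-property single slab, sudden boundary step 37 -> 80 degC
  slab <- material_layer("wall", 5, 1e-3, 4.2e-4, 5.0)
  hist <- data.frame(time = c(0, 1000), temp = c(80, 80))
  fld <- solve_heat(slab, history = hist,
                    config = thermal_config(dr = 0.01, dt = 0.005),
                    duration = 5)
  alpha <- 4.2e-4 / (1e-3 * 5)
  erfc <- function(z) 2 * stats::pnorm(z * sqrt(2), lower.tail = FALSE)
  pts <- expand.grid(x = c(0.05, 0.1, 0.2, 0.3, 0.5, 0.8, 1.2),
                     t = c(0.5, 1, 2, 5))
  for (i in seq_len(nrow(pts))) {
    ix <- which.min(abs(fld$depths - pts$x[i]))
    it <- which.min(abs(fld$times - pts$t[i]))
    exact <- 37 + (80 - 37) * erfc(pts$x[i] / (2 * sqrt(alpha * pts$t[i])))
    expect_lt(abs(fld$temps[it, ix] - exact), 0.2)
  }
})

test_that("steady state with both boundaries fixed is linear (planar, constant c)", {
  slab <- material_layer("wall", 0.5, 1e-3, 4.2e-4, 5.0)
  hist <- data.frame(time = c(0, 500), temp = c(80, 80))
  fld <- solve_heat(slab, history = hist,
                    config = thermal_config(dr = 0.01, dt = 0.05, outer_temp = 37),
                    duration = 120)
  final <- fld$temps[nrow(fld$temps), ]
  linear <- 80 + (37 - 80) * fld$depths / 0.5
  expect_equal(final, linear, tolerance = 1e-3)
})

test_that("peak temperature per depth behaves as an elementwise maximum", {
  h <- temperature_history(heating_protocol(37), dt = 0.1)
  setup <- fast_thermal_setup()
  f <- solve_heat(h, setup$layers, setup$config, duration = 5)
  expect_equal(peak_temperature_by_depth(f),
               rep(37, length(f$depths)))
  # monotone-in-time heating at every node: peak equals the final row
  slab <- material_layer("wall", 0.5, 1e-3, 4.2e-4, 5.0)
  hist <- data.frame(time = c(0, 500), temp = c(80, 80))
  fld <- solve_heat(slab, history = hist,
                    config = thermal_config(dr = 0.01, dt = 0.05,
                                            outer_boundary = "insulated"),
                    duration = 20)
  expect_true(all(apply(fld$temps, 2, function(v) all(diff(v) >= -1e-9))))
  expect_equal(peak_temperature_by_depth(fld), fld$temps[nrow(fld$temps), ])
  # any field: peaks never fall below the 37 degC initial row
  h2 <- temperature_history(heating_protocol(70), dt = 0.1)
  f2 <- solve_heat(h2, setup$layers, setup$config, duration = 30)
  expect_true(all(peak_temperature_by_depth(f2) >= 37 - 1e-9))
})

test_that("discrete maximum principle holds on a heating run", {
  h <- temperature_history(heating_protocol(85), dt = 0.1)
  setup <- fast_thermal_setup()
  f <- solve_heat(h, setup$layers, setup$config)
  lo <- min(min(h$temp), 37)
  hi <- max(h$temp)
  expect_gte(min(f$temps), lo - 1e-9)
  expect_lte(max(f$temps), hi + 1e-9)
})

test_that("heated depth is zero when the threshold is never reached", {
  h <- temperature_history(heating_protocol(85), dt = 0.1)
  setup <- fast_thermal_setup()
  f <- solve_heat(h, setup$layers, setup$config, duration = 45)
  expect_identical(heated_depth(f, threshold = 200), 0)
  expect_gt(heated_depth(f, threshold = 60), 0)
})

test_that("heated depth is nondecreasing in balloon peak temperature and heating time", {
  setup <- fast_thermal_setup()
  d_by_temp <- vapply(seq(60, 90, by = 5), heated_depth_at, 0, setup = setup)
  expect_true(all(diff(d_by_temp) >= 0))
  d_by_time <- vapply(c(10, 15, 20), function(ht)
    heated_depth_at(75, heating_time = ht, setup = setup, duration = ht + 30), 0)
  expect_true(all(diff(d_by_time) >= 0))
})

test_that("explicit scheme agrees with implicit and enforces its stability bound", {
  slab <- material_layer("wall", 0.1, 1e-3, 4.2e-4, 5.0)
  hist <- data.frame(time = c(0, 100), temp = c(60, 60))
  cfg_ex <- thermal_config(dr = 0.01, dt = 2e-4, scheme = "explicit")
  cfg_im <- thermal_config(dr = 0.01, dt = 2e-4, scheme = "implicit")
  f_ex <- solve_heat(slab, history = hist, config = cfg_ex, duration = 1)
  f_im <- solve_heat(slab, history = hist, config = cfg_im, duration = 1)
  # compare once the sudden-step startup transient has passed
  settled <- f_ex$times > 0.1
  expect_lt(max(abs(f_ex$temps[settled, ] - f_im$temps[settled, ])), 0.05)
  # too-large dt is refused with the admissible bound named
  cfg_bad <- thermal_config(dr = 0.01, dt = 0.01, scheme = "explicit")
  err <- expect_error(solve_heat(slab, history = hist, config = cfg_bad,
                                 duration = 1),
                      class = "smcdeform_stability_error")
  expect_match(conditionMessage(err), "maximum admissible dt")
})

test_that("temperatures outside the specific-heat table raise a band error", {
  slab <- arterial_wall_layer(0.5)
  hist <- data.frame(time = c(0, 100), temp = c(95, 95))
  expect_error(solve_heat(slab, history = hist,
                          config = thermal_config(dr = 0.01, dt = 0.05),
                          duration = 5),
               class = "smcdeform_band_error")
})

test_that("mesh and layer validation is enforced", {
  slab <- material_layer("wall", 0.517, 1e-3, 4.2e-4, 5.0)
  hist <- data.frame(time = c(0, 100), temp = c(50, 50))
  expect_error(solve_heat(slab, history = hist,
                          config = thermal_config(dr = 0.01, dt = 0.05),
                          duration = 5),
               "must divide")
  expect_error(material_layer("x", 0.5, 1e-3, 4.2e-4,
                              data.frame(lower = c(-Inf, 50), upper = c(40, 90),
                                         value = c(5, 6))),
               "contiguous")
  # history shorter than the requested span
  expect_error(solve_heat(material_layer("wall", 0.5, 1e-3, 4.2e-4, 5.0),
                          history = data.frame(time = c(0, 10), temp = c(50, 50)),
                          config = thermal_config(dr = 0.01, dt = 0.05),
                          duration = 50),
               "does not cover")
})

test_that("cylindrical geometry reduces to planar for a thin shell at large radius", {
  slab <- material_layer("wall", 0.2, 1e-3, 4.2e-4, 5.0)
  hist <- data.frame(time = c(0, 100), temp = c(70, 70))
  f_pl <- solve_heat(slab, history = hist,
                     config = thermal_config(dr = 0.005, dt = 0.02),
                     duration = 10)
  f_cy <- solve_heat(slab, history = hist,
                     config = thermal_config(dr = 0.005, dt = 0.02,
                                             geometry = "cylindrical",
                                             inner_radius = 100),
                     duration = 10)
  expect_lt(max(abs(f_pl$temps - f_cy$temps)), 0.02)
  # at a realistic radius curvature cools the outer wall slightly faster
  f_cy2 <- solve_heat(slab, history = hist,
                      config = thermal_config(dr = 0.005, dt = 0.02,
                                              geometry = "cylindrical",
                                              inner_radius = 0.73),
                      duration = 10)
  expect_false(isTRUE(all.equal(f_pl$temps, f_cy2$temps, tolerance = 1e-4)))
})
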