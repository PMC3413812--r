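# Shared fixtures: small, fast configurations used across test files.

# small vessel so rendered unit-test images stay small
small_geometry <- function() {
  vessel_geometry(inner_radius = 0.25, wall_thickness = 0.18)
}

small_cohort_config <- function(...) {
  args <- list(...)
  defaults <- list(geometry = small_geometry(),
                   nuclei_per_specimen = 30,
                   rng_seed = 11)
  do.call(cohort_config, utils::modifyList(defaults, args))
}

# default ex-vivo geometry (porcine carotid)
exvivo_geometry <- function() {
  vessel_geometry(inner_diameter = 1.46, wall_thickness = 0.54)
}

# coarse but valid conduction setup for fast unit tests (thicknesses rounded
# to multiples of the coarser mesh)
fast_thermal_setup <- function() {
  calibrated_thermal_setup(film_thickness = 0.075, tissue_thickness = 0.975,
                           dr = 0.005, dt = 0.1)
}

# brute-force pixel-moment oracle: scalar loops, no matrix algebra, kept
# deliberately independent of fit_ellipse()'s vectorised implementation
oracle_ellipse_axes <- function(coords, pixel_size) {
  n <- nrow(coords)
  sx <- 0; sy <- 0
  for (i in seq_len(n)) {
    sy <- sy + coords[i, 1]
    sx <- sx + coords[i, 2]
  }
  mx <- sx / n; my <- sy / n
  sxx <- 0; syy <- 0; sxy <- 0
  for (i in seq_len(n)) {
    dx <- coords[i, 2] - mx
    dy <- coords[i, 1] - my
    sxx <- sxx + dx * dx
    syy <- syy + dy * dy
    sxy <- sxy + dx * dy
  }
  mu20 <- sxx / n; mu02 <- syy / n; mu11 <- sxy / n
  # eigenvalues of [[mu20, mu11], [mu11, mu02]] via the quadratic formula
  root <- sqrt((mu20 - mu02)^2 / 4 + mu11^2)
  l1 <- (mu20 + mu02) / 2 + root
  l2 <- (mu20 + mu02) / 2 - root
  list(long = 4 * sqrt(l1) * pixel_size,
       short = 4 * sqrt(l2) * pixel_size)
}

# rasterise one ellipse into a matrix (independent of render_histology_image)
raster_ellipse <- function(n, cx, cy, a_px, b_px, phi) {
  img <- matrix(1, n, n)
  for (r in seq_len(n)) {
    for (cl in seq_len(n)) {
      dx <- cl - cx
      dy <- r - cy
      u <- dx * cos(phi) + dy * sin(phi)
      v <- -dx * sin(phi) + dy * cos(phi)
      if ((u / a_px)^2 + (v / b_px)^2 <= 1) img[r, cl] <- 0.15
    }
  }
  img
}
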