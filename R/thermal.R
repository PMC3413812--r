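#' Material layer for the conduction model
#'
#' A homogeneous layer of the 1-D conduction stack (balloon film, arterial
#' wall). The specific heat may be a single value or a piecewise-constant
#' table over temperature bands: the apparent-heat-capacity device by which
#' the latent heat of collagen thermal denaturation is folded into an
#' ordinary conduction solver.
#'
#' @param name layer name.
#' @param thickness layer thickness, mm.
#' @param density g/mm^3.
#' @param conductivity W/(mm*degC).
#' @param specific_heat either a single number (J/(g*degC)) or a data frame
#'   with columns `lower`, `upper` (degC, contiguous bands; use -Inf/Inf for
#'   open ends) and `value` (J/(g*degC)).
#' @return an object of class `material_layer`.
#' @export
material_layer <- function(name, thickness, density, conductivity,
                           specific_heat) {
  check_number(thickness, "thickness", positive = TRUE)
  check_number(density, "density", positive = TRUE)
  check_number(conductivity, "conductivity", positive = TRUE)
  if (is.numeric(specific_heat) && length(specific_heat) == 1L) {
    specific_heat <- data.frame(lower = -Inf, upper = Inf,
                                value = specific_heat)
  }
  stopifnot(is.data.frame(specific_heat),
            all(c("lower", "upper", "value") %in% names(specific_heat)))
  sh <- specific_heat[order(specific_heat$lower), , drop = FALSE]
  if (any(sh$value <= 0)) abort_validation("specific heat values must be > 0")
  if (nrow(sh) > 1L &&
      any(abs(sh$lower[-1L] - sh$upper[-nrow(sh)]) > 1e-9)) {
    abort_validation(sprintf(
      "specific-heat bands of layer '%s' are not contiguous", name))
  }
  structure(list(name = name, thickness = thickness, density = density,
                 conductivity = conductivity, specific_heat = sh),
            class = "material_layer")
}

#' Arterial wall layer (thermal properties)
#'
#' Arterial wall with density 1.0e-3 g/mm^3, conductivity 4.2e-4 W/(mm*degC)
#' and the piecewise specific heat 5.0 (<40 degC), 5.6 (40-50), 6.7 (50-60),
#' 8.2 (60-70), 11.0 (70-80), 12.0 (80-90 degC) reflecting collagen thermal
#' denaturation. Temperatures at or above 90 degC are outside the table and
#' raise an error in the solver.
#'
#' @param thickness layer thickness, mm (media is 0.54 mm; the calibrated
#'   conduction domain extends further, see [calibrated_thermal_setup()]).
#' @return a [material_layer()].
#' @export
arterial_wall_layer <- function(thickness = 0.54) {
  material_layer(
    name = "wall", thickness = thickness,
    density = 1.0e-3, conductivity = 4.2e-4,
    specific_heat = data.frame(
      lower = c(-Inf, 40, 50, 60, 70, 80),
      upper = c(40, 50, 60, 70, 80, 90),
      value = c(5.0, 5.6, 6.7, 8.2, 11.0, 12.0)))
}

#' Balloon film layer (thermal properties)
#'
#' Balloon film with density 1.0e-3 g/mm^3, conductivity 2.4e-4 W/(mm*degC)
#' and constant specific heat 2.0 J/(g*degC).
#'
#' @param thickness film thickness, mm.
#' @return a [material_layer()].
#' @export
balloon_film_layer <- function(thickness = 0.05) {
  material_layer(name = "film", thickness = thickness,
                 density = 1.0e-3, conductivity = 2.4e-4,
                 specific_heat = 2.0)
}

# piecewise-constant specific heat lookup; errors on table gaps
specific_heat_at <- function(layer, temps) {
  sh <- layer$specific_heat
  idx <- findInterval(temps, c(sh$lower[1L], sh$upper))
  bad <- idx < 1L | idx > nrow(sh)
  if (any(bad)) {
    t_bad <- temps[bad][1L]
    abort_validation(sprintf(
      "temperature %.2f degC is outside the specific-heat table of layer '%s' (bands cover %g to %g degC)",
      t_bad, layer$name, sh$lower[1L], sh$upper[nrow(sh)]),
      class = "smcdeform_band_error")
  }
  sh$value[idx]
}

#' Configuration of the 1-D conduction solver
#'
#' @param dr mesh spacing, mm; must divide every layer thickness.
#' @param dt time step, s.
#' @param outer_boundary `"fixed"` (Dirichlet at `outer_temp`, the 37 degC
#'   bath of the ex-vivo setting) or `"insulated"` (zero flux, for
#'   sensitivity analysis).
#' @param outer_temp outer boundary temperature, degC.
#' @param initial_temp initial temperature everywhere, degC.
#' @param geometry `"planar"` (default; the wall is thin relative to the
#'   vessel radius) or `"cylindrical"`.
#' @param inner_radius luminal radius at the film inner surface, mm; used
#'   only for cylindrical geometry.
#' @param scheme `"implicit"` (backward Euler, unconditionally stable) or
#'   `"explicit"` (forward Euler, used as a cross-check; its stability
#'   criterion is enforced, not assumed).
#' @return an object of class `thermal_config`.
#' @export
thermal_config <- function(dr = 0.0025, dt = 0.025,
                           outer_boundary = c("fixed", "insulated"),
                           outer_temp = 37, initial_temp = 37,
                           geometry = c("planar", "cylindrical"),
                           inner_radius = 0.73,
                           scheme = c("implicit", "explicit")) {
  check_number(dr, "dr", positive = TRUE)
  check_number(dt, "dt", positive = TRUE)
  check_number(outer_temp, "outer_temp")
  check_number(initial_temp, "initial_temp")
  check_number(inner_radius, "inner_radius", positive = TRUE)
  structure(list(dr = dr, dt = dt,
                 outer_boundary = match.arg(outer_boundary),
                 outer_temp = outer_temp, initial_temp = initial_temp,
                 geometry = match.arg(geometry),
                 inner_radius = inner_radius,
                 scheme = match.arg(scheme)),
            class = "thermal_config")
}

#' Calibrated conduction setup reproducing the study's thermal estimates
#'
#' The conduction stack used for the heated-depth estimates: the balloon film
#' plus arterial tissue (media and the adventitia/surrounding tissue, which
#' shares the wall's thermal properties) bounded by the 37 degC bath. Film
#' thickness and total tissue thickness are the calibration parameters of the
#' model; the shipped values were calibrated once against the study's two
#' heated-depth endpoints (0.05 mm at a 65 degC balloon peak and 0.42 mm at
#' 85 degC, 15 s heating) and are versioned with the package.
#'
#' @param film_thickness balloon film thickness, mm.
#' @param tissue_thickness total tissue thickness from the film to the bath,
#'   mm (media 0.54 mm plus surrounding tissue).
#' @param dr,dt mesh spacing (mm) and time step (s).
#' @return a list with elements `layers` (film + wall [material_layer()]s)
#'   and `config` (a [thermal_config()]).
#' @export
calibrated_thermal_setup <- function(film_thickness = 0.0775,
                                     tissue_thickness = 0.9725,
                                     dr = 0.0025, dt = 0.025) {
  list(layers = list(balloon_film_layer(film_thickness),
                     arterial_wall_layer(tissue_thickness)),
       config = thermal_config(dr = dr, dt = dt))
}

# tridiagonal solve (Thomas algorithm); a sub-, b main, cc super-diagonal
solve_tridiag <- function(a, b, cc, d) {
  n <- length(d)
  cp <- numeric(n)
  dp <- numeric(n)
  cp[1L] <- cc[1L] / b[1L]
  dp[1L] <- d[1L] / b[1L]
  if (n > 1L) {
    for (i in 2:n) {
      m <- b[i] - a[i] * cp[i - 1L]
      cp[i] <- cc[i] / m
      dp[i] <- (d[i] - a[i] * dp[i - 1L]) / m
    }
  }
  x <- numeric(n)
  x[n] <- dp[n]
  if (n > 1L) for (i in (n - 1L):1L) x[i] <- dp[i] - cp[i] * x[i + 1L]
  x
}

#' Solve 1-D transient heat conduction through layered tissue
#'
#' Finite-volume conduction solver on a uniform grid through the layer stack,
#' with the balloon temperature history imposed as a Dirichlet condition on
#' the inner (film) surface. The specific heat of each node is re-evaluated
#' every step from the current temperature's band (explicit lagging of the
#' apparent heat capacity); conductivity is per layer. Backward Euler is the
#' default scheme; the explicit scheme is provided as a cross-check and
#' refuses time steps violating its stability bound.
#'
#' @param history a [temperature_history()] (or data frame with `time`,
#'   `temp`) covering the full simulation span.
#' @param layers list of [material_layer()]s, luminal side first.
#' @param config a [thermal_config()].
#' @param duration simulation span, s; defaults to the history's span.
#' @return an object of class `temperature_field`: list with `times` (s),
#'   `depths` (mm from the luminal film surface), `temps` (time x depth
#'   matrix, degC) and `film_thickness` (mm of leading non-wall layers,
#'   0 for a single-layer stack).
#' @export
solve_heat <- function(history, layers, config = thermal_config(),
                       duration = NULL) {
  stopifnot(is.data.frame(history), all(c("time", "temp") %in% names(history)))
  if (inherits(layers, "material_layer")) layers <- list(layers)
  stopifnot(length(layers) >= 1L,
            all(vapply(layers, inherits, TRUE, "material_layer")),
            inherits(config, "thermal_config"))
  dr <- config$dr
  dt <- config$dt
  duration <- duration %||% max(history$time)
  if (max(history$time) < duration - 1e-9) {
    abort_validation("`history` does not cover the requested simulation span")
  }

  # grid: nodes at layer interfaces, dr must divide each layer
  ncell_layer <- vapply(layers, function(l) l$thickness / dr, 0)
  if (any(abs(ncell_layer - round(ncell_layer)) > 1e-8)) {
    abort_validation("`dr` must divide every layer thickness")
  }
  ncell_layer <- as.integer(round(ncell_layer))
  n_cells <- sum(ncell_layer)
  n_nodes <- n_cells + 1L
  x <- seq(0, by = dr, length.out = n_nodes)
  cell_layer <- rep(seq_along(layers), ncell_layer)
  k_cell <- vapply(layers, `[[`, 0, "conductivity")[cell_layer]
  rho_cell <- vapply(layers, `[[`, 0, "density")[cell_layer]

  # time stepping admissibility (checked, not assumed)
  proto <- attr(history, "protocol")
  tau_forcing <- if (!is.null(proto)) {
    min(proto$ramp_time_constant, proto$cooling_time_constant)
  } else {
    max(stats::median(diff(history$time)) * 4, duration / 200)
  }
  if (config$scheme == "implicit" && dt > tau_forcing / 2) {
    abort_validation(sprintf(
      "time step dt = %g s is too coarse to resolve the boundary forcing; maximum admissible dt is %g s",
      dt, tau_forcing / 2))
  }

  # cylindrical weights (all 1 for planar)
  if (config$geometry == "cylindrical") {
    r_node <- config$inner_radius + x
    w_face <- config$inner_radius + (x[-n_nodes] + dr / 2) # faces between nodes
    w_half_lo <- r_node - dr / 4  # half-cell centroids below/above each node
    w_half_hi <- r_node + dr / 4
  } else {
    w_face <- rep(1, n_cells)
    w_half_lo <- w_half_hi <- rep(1, n_nodes)
  }
  kf <- k_cell * w_face # conductance weight per face / dr

  bfun <- stats::approxfun(history$time, history$temp, rule = 2)
  times <- seq(0, duration, by = dt)
  temps <- matrix(NA_real_, nrow = length(times), ncol = n_nodes)
  temp <- rep(config$initial_temp, n_nodes)
  temp[1L] <- bfun(0)
  temps[1L, ] <- temp
  insulated <- config$outer_boundary == "insulated"

  # node heat capacity per unit area: half-cell on each side, c from the
  # node's current temperature within each adjacent layer's band table
  node_capacity <- function(tv) {
    cap <- numeric(n_nodes)
    for (li in seq_along(layers)) {
      nodes_lo <- which(cell_layer == li)        # node below each cell
      nodes_hi <- nodes_lo + 1L                  # node above each cell
      c_lo <- specific_heat_at(layers[[li]], tv[nodes_lo])
      c_hi <- specific_heat_at(layers[[li]], tv[nodes_hi])
      rho <- layers[[li]]$density
      cap[nodes_lo] <- cap[nodes_lo] +
        0.5 * dr * rho * c_lo * w_half_hi[nodes_lo]
      cap[nodes_hi] <- cap[nodes_hi] +
        0.5 * dr * rho * c_hi * w_half_lo[nodes_hi]
    }
    cap
  }

  interior <- 2:(if (insulated) n_nodes else n_nodes - 1L)
  ni <- length(interior)
  k_lo <- kf[interior - 1L] / dr         # conductance across the face below
  k_hi <- if (insulated) {
    c(kf[interior[-ni]] / dr, 0)         # zero flux at the outer face
  } else {
    kf[interior] / dr
  }

  for (s in seq_along(times)[-1L]) {
    t_new <- times[s]
    cap <- node_capacity(temp)[interior]
    tb <- bfun(t_new)
    if (config$scheme == "implicit") {
      b <- cap / dt + k_lo + k_hi
      a <- c(0, -k_lo[-1L])
      cc <- c(-k_hi[-ni], 0)
      d <- cap / dt * temp[interior]
      d[1L] <- d[1L] + k_lo[1L] * tb
      if (!insulated) d[ni] <- d[ni] + k_hi[ni] * config$outer_temp
      temp[interior] <- solve_tridiag(a, b, cc, d)
    } else {
      dt_max <- min(cap / (k_lo + k_hi))
      if (dt > dt_max) {
        abort_validation(sprintf(
          "explicit scheme unstable at dt = %g s; maximum admissible dt is %g s",
          dt, dt_max), class = "smcdeform_stability_error")
      }
      t_lo <- temp[interior - 1L]
      # value at the node above; for the insulated end it multiplies k_hi == 0
      t_hi <- c(temp[interior[-ni] + 1L],
                if (insulated) 0 else config$outer_temp)
      flux <- k_hi * (t_hi - temp[interior]) - k_lo * (temp[interior] - t_lo)
      temp[interior] <- temp[interior] + dt / cap * flux
    }
    temp[1L] <- tb
    if (!insulated) temp[n_nodes] <- config$outer_temp
    temps[s, ] <- temp
  }

  film_th <- if (length(layers) > 1L) layers[[1L]]$thickness else 0
  structure(list(times = times, depths = x, temps = temps,
                 film_thickness = film_th, config = config),
            class = "temperature_field")
}

#' @export
print.temperature_field <- function(x, ...) {
  cat(sprintf(
    "Temperature field: %d time steps x %d depth nodes (%.3f mm, film %.3f mm)\n",
    length(x$times), length(x$depths), max(x$depths), x$film_thickness))
  cat(sprintf("  temperature range %.1f to %.1f degC\n",
              min(x$temps), max(x$temps)))
  invisible(x)
}

#' @export
plot.temperature_field <- function(x, ...) {
  graphics::image(x$times, x$depths, x$temps,
                  xlab = "time (s)", ylab = "depth from luminal surface (mm)",
                  col = grDevices::hcl.colors(64, "Inferno"), ...)
  invisible(x)
}

#' Peak temperature reached at each depth
#'
#' Elementwise maximum over time of the simulated field.
#'
#' @param field a `temperature_field` from [solve_heat()].
#' @return numeric vector of per-depth maxima, degC (one per depth node).
#' @export
peak_temperature_by_depth <- function(field) {
  stopifnot(inherits(field, "temperature_field"))
  if (length(field$times) == 0L || length(field$depths) == 0L) {
    abort_validation("empty temperature field")
  }
  apply(field$temps, 2L, max)
}

#' Depth of wall tissue heated above a threshold
#'
#' Largest depth into the wall (the balloon film is excluded) whose
#' peak-over-time temperature reaches `threshold`, with linear interpolation
#' between mesh nodes; 0 if no wall tissue reaches it. This is the extent of
#' collagen thermal denaturation when `threshold` is 60 degC.
#'
#' @param field a `temperature_field` from [solve_heat()].
#' @param threshold temperature threshold, degC (default 60, the onset of
#'   collagen thermal denaturation).
#' @return depth, mm.
#' @export
heated_depth <- function(field, threshold = 60) {
  stopifnot(inherits(field, "temperature_field"))
  check_number(threshold, "threshold")
  peaks <- peak_temperature_by_depth(field)
  wall <- field$depths >= field$film_thickness - 1e-12
  d <- field$depths[wall] - field$film_thickness
  p <- peaks[wall]
  hot <- which(p >= threshold)
  if (length(hot) == 0L) return(0)
  i <- max(hot)                       # deepest node at/above threshold
  if (i == length(p)) return(d[i])    # exceeds through the whole domain
  # interpolate the crossing between node i and the first cooler node
  d[i] + (p[i] - threshold) / (p[i] - p[i + 1L]) * (d[i + 1L] - d[i])
}

#' Heated depth for a balloon peak temperature under the calibrated setup
#'
#' Convenience wrapper: builds the default protocol at the requested balloon
#' peak temperature, solves conduction under the calibrated setup, and
#' returns the wall depth heated above `threshold`. The simulation spans
#' heating plus 30 s, by which time every node has passed its maximum.
#'
#' @param t_peak balloon peak temperature, degC.
#' @param heating_time heating time, s.
#' @param setup list with `layers` and `config`, as from
#'   [calibrated_thermal_setup()].
#' @param threshold threshold temperature, degC.
#' @param duration simulation span, s.
#' @return depth, mm.
#' @examples
#' \donttest{
#' heated_depth_at(65)  # ~0.05 mm
#' }
#' @export
heated_depth_at <- function(t_peak, heating_time = 15,
                            setup = calibrated_thermal_setup(),
                            threshold = 60,
                            duration = heating_time + 30) {
  proto <- heating_protocol(t_peak, heating_time = heating_time)
  hist <- temperature_history(proto, dt = setup$config$dt)
  field <- solve_heat(hist, setup$layers, setup$config, duration = duration)
  heated_depth(field, threshold = threshold)
}
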