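#' Configuration of a synthetic specimen cohort
#'
#' Study-design parameters of the synthetic ex-vivo/in-vivo cohort: paired
#' before/after vessel cross-sections populated with elliptical SMC nuclei
#' oriented near-circumferentially. Defaults emulate the study conditions:
#' porcine carotid geometry (inner diameter 1.46 mm, media thickness
#' 0.54 mm), 6 specimens per balloon-temperature condition, ex-vivo
#' temperature range 60-75 degC.
#'
#' @param n_specimens_per_condition specimens per condition (default 6).
#' @param t_balloon_levels balloon peak temperatures, degC.
#' @param nuclei_per_specimen nuclei per specimen (default 100; the number
#'   measured per image is not documented and is configurable).
#' @param baseline_aspect_mean,baseline_aspect_sd mean and sd of the
#'   lognormal baseline nuclear aspect ratio (defaults 2.5, 0.4).
#' @param baseline_short_axis nuclear short axis, mm (default 0.008).
#' @param orientation_jitter_sd sd of nuclear orientation about the local
#'   circumferential direction, radians (default 0.1; SMCs are oriented
#'   low-angle spirally).
#' @param measurement_noise_cv coefficient of variation of the multiplicative
#'   lognormal measurement noise applied to nuclear axes at render time
#'   (default 0.02).
#' @param rng_seed integer seed; identical seeds give bit-identical cohorts.
#' @param geometry before-state [vessel_geometry()].
#' @param arm `"heating"` (area-conserving dilation deforms the nuclei) or
#'   `"conventional"` (plastic dilation; nuclear shape unchanged).
#' @param target_dilatation_rates optional numeric vector of explicit target
#'   dilatation rates, one specimen each; overrides the temperature levels
#'   and the dose-response link.
#' @param nuclei_radial_range optional `c(lo, hi)` restricting nucleus
#'   centroid radii, mm (e.g. a narrow band at mid-wall).
#' @param relaxation_factor fraction by which after-state nuclear deformation
#'   relaxes toward baseline (default 0: the stretched condition is
#'   maintained into the chronic phase).
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_specimens_per_condition = 6,
                          t_balloon_levels = c(60, 65, 70, 75),
                          nuclei_per_specimen = 100,
                          baseline_aspect_mean = 2.5,
                          baseline_aspect_sd = 0.4,
                          baseline_short_axis = 0.008,
                          orientation_jitter_sd = 0.1,
                          measurement_noise_cv = 0.02,
                          rng_seed = 1,
                          geometry = vessel_geometry(inner_diameter = 1.46,
                                                     wall_thickness = 0.54),
                          arm = c("heating", "conventional"),
                          target_dilatation_rates = NULL,
                          nuclei_radial_range = NULL,
                          relaxation_factor = 0) {
  check_number(n_specimens_per_condition, "n_specimens_per_condition", positive = TRUE)
  check_number(nuclei_per_specimen, "nuclei_per_specimen", positive = TRUE)
  check_number(baseline_aspect_mean, "baseline_aspect_mean", positive = TRUE)
  check_number(baseline_aspect_sd, "baseline_aspect_sd", nonnegative = TRUE)
  check_number(baseline_short_axis, "baseline_short_axis", positive = TRUE)
  check_number(orientation_jitter_sd, "orientation_jitter_sd", nonnegative = TRUE)
  check_number(measurement_noise_cv, "measurement_noise_cv", nonnegative = TRUE)
  check_number(relaxation_factor, "relaxation_factor", nonnegative = TRUE)
  stopifnot(inherits(geometry, "vessel_geometry"))
  if (baseline_aspect_mean < 1) {
    abort_validation("`baseline_aspect_mean` must be >= 1 (aspect ratio is long/short)")
  }
  structure(list(
    n_specimens_per_condition = as.integer(n_specimens_per_condition),
    t_balloon_levels = t_balloon_levels,
    nuclei_per_specimen = as.integer(nuclei_per_specimen),
    baseline_aspect_mean = baseline_aspect_mean,
    baseline_aspect_sd = baseline_aspect_sd,
    baseline_short_axis = baseline_short_axis,
    orientation_jitter_sd = orientation_jitter_sd,
    measurement_noise_cv = measurement_noise_cv,
    rng_seed = as.integer(rng_seed),
    geometry = geometry,
    arm = match.arg(arm),
    target_dilatation_rates = target_dilatation_rates,
    nuclei_radial_range = nuclei_radial_range,
    relaxation_factor = relaxation_factor),
    class = "cohort_config")
}

#' Dose-response link from balloon temperature to target dilatation rate
#'
#' The study ties the achievable dilatation to the softened (heated above
#' 60 degC) wall depth; it gives the mechanism, not a formula. The default
#' link is `dilatation_rate(T) = 1 + gain * heated_depth(T)` with the
#' calibrated conduction setup, `gain = 0.5 / 0.42` mm^-1 so the 85 degC
#' condition reaches a rate of ~1.5. Heated depths are cached per
#' temperature; any monotone function of T_balloon can be substituted.
#'
#' @param gain rate increase per mm of heated depth, mm^-1.
#' @param heating_time heating time, s.
#' @param setup conduction setup, see [calibrated_thermal_setup()].
#' @param threshold softening threshold, degC.
#' @return a function mapping T_balloon (degC) to a target dilatation rate.
#' @export
dose_response_link <- function(gain = 0.5 / 0.42, heating_time = 15,
                               setup = calibrated_thermal_setup(),
                               threshold = 60) {
  check_number(gain, "gain", nonnegative = TRUE)
  cache <- new.env(parent = emptyenv())
  function(t_balloon) {
    vapply(t_balloon, function(tb) {
      key <- sprintf("%.6g", tb)
      if (is.null(cache[[key]])) {
        cache[[key]] <- heated_depth_at(tb, heating_time = heating_time,
                                        setup = setup, threshold = threshold)
      }
      1 + gain * cache[[key]]
    }, 0)
  }
}

# Transform an ellipse (full axes, orientation from the circumferential
# direction) by the local in-plane stretch diag(lambda_theta, lambda_r) in
# the (tangential, radial) basis. Returns the exact deformed ellipse.
transform_ellipse <- function(long_axis, short_axis, psi,
                              lambda_theta, lambda_r) {
  a <- long_axis / 2
  b <- short_axis / 2
  cs <- cos(psi); sn <- sin(psi)
  # shape matrix M = R diag(a^2, b^2) R^T
  m11 <- a^2 * cs^2 + b^2 * sn^2
  m22 <- a^2 * sn^2 + b^2 * cs^2
  m12 <- (a^2 - b^2) * cs * sn
  # M' = F M F with F = diag(lt, lr)
  m11 <- m11 * lambda_theta^2
  m22 <- m22 * lambda_r^2
  m12 <- m12 * lambda_theta * lambda_r
  tr <- m11 + m22
  disc <- sqrt(pmax((m11 - m22)^2 + 4 * m12^2, 0))
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  psi_new <- atan2(2 * m12, m11 - m22) / 2  # principal axis angle
  list(long_axis = 2 * sqrt(l1), short_axis = 2 * sqrt(l2),
       orientation = psi_new)
}

#' Generate one paired before/after vessel phantom
#'
#' Samples elliptical SMC nuclei area-uniformly inside the media annulus
#' (with a simple overlap-rejection rule), oriented near-circumferentially,
#' then derives the after state from the before state through the
#' area-conserving deformation map (heating arm) or leaves nuclear shape
#' unchanged (conventional arm). Ground truth for both states is stored with
#' the phantom.
#'
#' @param config a [cohort_config()].
#' @param dilatation_rate target inner-diameter dilatation rate (>= 1).
#' @param seed integer seed for this specimen.
#' @param specimen_id,condition identifiers stored in the phantom.
#' @return an object of class `vessel_phantom` with `geometry_before`,
#'   `geometry_after`, `map`, and ground-truth data frames `nuclei_before`,
#'   `nuclei_after` (columns nucleus_id, centroid_r_mm, centroid_theta_rad,
#'   long_axis_mm, short_axis_mm, orientation_rad).
#' @export
generate_phantom <- function(config, dilatation_rate = 1, seed = config$rng_seed,
                             specimen_id = "S1", condition = NA_character_) {
  stopifnot(inherits(config, "cohort_config"))
  check_number(dilatation_rate, "dilatation_rate", positive = TRUE)
  if (dilatation_rate < 1 - 1e-12) {
    abort_validation("target dilatation rate < 1: the model does not shrink lumens")
  }
  geom <- config$geometry
  n <- config$nuclei_per_specimen
  ri <- geom$inner_radius
  ro <- outer_radius(geom)
  map <- if (config$arm == "heating") {
    dilate_area_conserving(geom, 2 * ri * dilatation_rate)
  } else {
    NULL
  }

  nuclei <- with_seed(seed, {
    sdlog <- sqrt(log(1 + (config$baseline_aspect_sd /
                             config$baseline_aspect_mean)^2))
    meanlog <- log(config$baseline_aspect_mean) - sdlog^2 / 2
    aspect <- pmax(1, stats::rlnorm(n, meanlog, sdlog))
    short <- rep(config$baseline_short_axis, n)
    long <- short * aspect
    psi <- stats::rnorm(n, 0, config$orientation_jitter_sd)

    # area-uniform positions with overlap rejection
    r_out <- theta_out <- numeric(n)
    x_acc <- y_acc <- l_acc <- numeric(0)
    for (j in seq_len(n)) {
      margin <- 1.25 * long[j] / 2
      lo <- ri + margin
      hi <- ro - margin
      if (!is.null(config$nuclei_radial_range)) {
        lo <- max(lo, config$nuclei_radial_range[1L])
        hi <- min(hi, config$nuclei_radial_range[2L])
      }
      if (lo >= hi) {
        abort_validation("nuclei do not fit inside the media annulus (radial range empty)")
      }
      ok <- FALSE
      for (try in seq_len(400L)) {
        r <- sqrt(stats::runif(1, lo^2, hi^2))
        th <- stats::runif(1, 0, 2 * pi)
        x <- r * cos(th); y <- r * sin(th)
        clear <- length(x_acc) == 0 ||
          all((x - x_acc)^2 + (y - y_acc)^2 >
                (1.1 * (long[j] / 2 + l_acc))^2)
        if (clear && !is.null(map)) {
          # the deformed nucleus must still fit inside the after-annulus
          ls <- local_stretch(map, r)
          tr <- transform_ellipse(long[j], short[j], psi[j],
                                  ls$lambda_theta, ls$lambda_r)
          ra <- map_radius(map, r)
          clear <- (ra - 1.1 * tr$long_axis / 2 > map$after$inner_radius) &&
            (ra + 1.1 * tr$long_axis / 2 < outer_radius(map$after))
        }
        if (clear) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        abort_validation("could not place nuclei without overlap; reduce `nuclei_per_specimen` or nucleus size")
      }
      r_out[j] <- r; theta_out[j] <- th
      x_acc <- c(x_acc, x); y_acc <- c(y_acc, y)
      l_acc <- c(l_acc, long[j] / 2)
    }
    data.frame(nucleus_id = seq_len(n),
               centroid_r_mm = r_out, centroid_theta_rad = theta_out,
               long_axis_mm = long, short_axis_mm = short,
               orientation_rad = psi)
  })

  if (config$arm == "heating") {
    geom_after <- map$after
    ls <- local_stretch(map, nuclei$centroid_r_mm)
    lt <- ls$lambda_theta
    lr <- ls$lambda_r
    if (config$relaxation_factor > 0) {
      f <- 1 - config$relaxation_factor
      lt <- lt^f
      lr <- lr^f
    }
    tr <- transform_ellipse(nuclei$long_axis_mm, nuclei$short_axis_mm,
                            nuclei$orientation_rad, lt, lr)
    nuclei_after <- data.frame(
      nucleus_id = nuclei$nucleus_id,
      centroid_r_mm = map_radius(map, nuclei$centroid_r_mm),
      centroid_theta_rad = nuclei$centroid_theta_rad,
      long_axis_mm = tr$long_axis, short_axis_mm = tr$short_axis,
      orientation_rad = tr$orientation)
  } else {
    # conventional balloon: plastic dilation; SMC nuclear shape unchanged
    map <- NULL
    geom_after <- geom
    nuclei_after <- nuclei
  }

  structure(list(specimen_id = specimen_id, condition = condition,
                 arm = config$arm,
                 target_dilatation_rate = dilatation_rate,
                 geometry_before = geom, geometry_after = geom_after,
                 map = map,
                 nuclei_before = nuclei, nuclei_after = nuclei_after,
                 measurement_noise_cv = config$measurement_noise_cv,
                 seed = as.integer(seed)),
            class = "vessel_phantom")
}

#' @export
print.vessel_phantom <- function(x, ...) {
  cat(sprintf(
    "Vessel phantom %s (%s arm%s): %d nuclei, target dilatation rate %.3f\n",
    x$specimen_id, x$arm,
    if (is.na(x$condition)) "" else paste0(", ", x$condition),
    nrow(x$nuclei_before), x$target_dilatation_rate))
  print(x$geometry_before)
  invisible(x)
}

#' Generate a synthetic cohort of paired vessel phantoms
#'
#' One paired before/after phantom per specimen. Target dilatation rates come
#' either from explicit `target_dilatation_rates` in the config (one
#' specimen each) or from the dose-response `link` evaluated at each
#' balloon-temperature level (`n_specimens_per_condition` specimens per
#' level). Per-specimen RNG substreams are derived from the cohort seed by
#' fixed offsets, so the cohort is bit-identical for a fixed seed.
#'
#' @param config a [cohort_config()].
#' @param link function mapping T_balloon to target dilatation rate; default
#'   [dose_response_link()]. Ignored when explicit rates are given or for the
#'   conventional arm.
#' @return a list of [generate_phantom()] objects, class `vessel_cohort`.
#' @export
generate_cohort <- function(config, link = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$target_dilatation_rates)) {
    rates <- config$target_dilatation_rates
    conditions <- sprintf("rate=%.4g", rates)
  } else if (config$arm == "conventional") {
    n_tot <- config$n_specimens_per_condition * length(config$t_balloon_levels)
    rates <- rep(1, n_tot)
    conditions <- rep(sprintf("%g", config$t_balloon_levels),
                      each = config$n_specimens_per_condition)
  } else {
    if (is.null(link)) link <- dose_response_link()
    per_level <- link(config$t_balloon_levels)
    if (any(per_level < 1 - 1e-12)) {
      abort_validation("dose-response link returned a dilatation rate < 1")
    }
    rates <- rep(per_level, each = config$n_specimens_per_condition)
    conditions <- rep(sprintf("%g", config$t_balloon_levels),
                      each = config$n_specimens_per_condition)
  }
  phantoms <- vector("list", length(rates))
  for (i in seq_along(rates)) {
    phantoms[[i]] <- generate_phantom(
      config, dilatation_rate = rates[i],
      seed = config$rng_seed + 1009L * i,
      specimen_id = sprintf("S%02d", i),
      condition = conditions[i])
  }
  structure(phantoms, class = c("vessel_cohort", "list"))
}

#' Ground truth of a cohort as one data frame
#'
#' @param cohort a `vessel_cohort` (or single phantom).
#' @return data frame with columns specimen_id, state (before/after),
#'   nucleus_id, centroid_r_mm, centroid_theta_rad, long_axis_mm,
#'   short_axis_mm, orientation_rad.
#' @export
cohort_ground_truth <- function(cohort) {
  if (inherits(cohort, "vessel_phantom")) cohort <- list(cohort)
  do.call(rbind, lapply(cohort, function(ph) {
    rbind(cbind(specimen_id = ph$specimen_id, state = "before",
                ph$nuclei_before),
          cbind(specimen_id = ph$specimen_id, state = "after",
                ph$nuclei_after))
  }))
}

#' Write cohort ground truth to CSV
#'
#' @param cohort a `vessel_cohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(cohort, path) {
  utils::write.csv(cohort_ground_truth(cohort), path, row.names = FALSE)
  invisible(path)
}
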