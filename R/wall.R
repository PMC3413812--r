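#' Annular vessel geometry
#'
#' Cross-sectional geometry of the arterial wall: a circular annulus defined
#' by its inner (luminal) radius and wall thickness, at a fixed axial stretch
#' (the arteries are held at 1.2-fold of their in-situ length before, during
#' and after dilatation, so all deformation is in-plane).
#'
#' @param inner_radius luminal radius, mm (alternatively give
#'   `inner_diameter`).
#' @param wall_thickness media thickness, mm.
#' @param axial_stretch axial stretch, dimensionless (default 1.2).
#' @param inner_diameter luminal diameter, mm; overrides `inner_radius`.
#' @return an object of class `vessel_geometry`.
#' @examples
#' vessel_geometry(inner_diameter = 1.46, wall_thickness = 0.54)
#' @export
vessel_geometry <- function(inner_radius = NULL, wall_thickness,
                            axial_stretch = 1.2, inner_diameter = NULL) {
  if (!is.null(inner_diameter)) {
    check_number(inner_diameter, "inner_diameter", positive = TRUE)
    inner_radius <- inner_diameter / 2
  }
  check_number(inner_radius, "inner_radius", positive = TRUE)
  check_number(wall_thickness, "wall_thickness", positive = TRUE)
  check_number(axial_stretch, "axial_stretch", positive = TRUE)
  structure(list(inner_radius = inner_radius,
                 wall_thickness = wall_thickness,
                 axial_stretch = axial_stretch),
            class = "vessel_geometry")
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat(sprintf(
    "Vessel geometry: inner diameter %.3f mm, wall thickness %.3f mm, axial stretch %.2f\n",
    2 * x$inner_radius, x$wall_thickness, x$axial_stretch))
  invisible(x)
}

#' Outer radius of a vessel geometry
#' @param geom a [vessel_geometry()].
#' @return outer radius, mm.
#' @export
outer_radius <- function(geom) geom$inner_radius + geom$wall_thickness

#' In-plane wall cross-sectional area of a vessel geometry
#' @param geom a [vessel_geometry()].
#' @return annulus area, mm^2.
#' @export
annulus_area <- function(geom) {
  pi * (outer_radius(geom)^2 - geom$inner_radius^2)
}

#' Area-conserving dilation of the vessel wall
#'
#' Dilates the annulus to a new inner diameter while conserving the in-plane
#' wall cross-sectional area exactly (the wall is incompressible and the
#' axial stretch is held fixed, so no tissue volume is gained or lost:
#' dilatation without plastic deformation). The after-thickness follows from
#' annulus-area equality,
#' \deqn{t' = \sqrt{r'^2 + 2 r t + t^2} - r',}
#' and every interior radius maps by equating enclosed wall areas,
#' \deqn{r_{after}(r) = \sqrt{r'^2 + r^2 - r_i^2}.}
#'
#' @param geom a [vessel_geometry()], the before state.
#' @param new_inner_diameter luminal diameter after dilation, mm; must not be
#'   smaller than the current diameter.
#' @return an object of class `deformation_map` with elements `before`,
#'   `after` (both [vessel_geometry()]) and the radial correspondence.
#' @examples
#' g <- vessel_geometry(inner_diameter = 1.46, wall_thickness = 0.54)
#' m <- dilate_area_conserving(g, 2.0)
#' m$after$wall_thickness            # ~0.442 mm
#' annulus_area(m$after) / annulus_area(m$before)  # exactly 1
#' @export
dilate_area_conserving <- function(geom, new_inner_diameter) {
  stopifnot(inherits(geom, "vessel_geometry"))
  check_number(new_inner_diameter, "new_inner_diameter", positive = TRUE)
  r1 <- geom$inner_radius
  t1 <- geom$wall_thickness
  r2 <- new_inner_diameter / 2
  if (r2 < r1 - 1e-12) {
    abort_validation("shrinking the lumen is outside the model's scope (new_inner_diameter < current)")
  }
  t2 <- sqrt(r2^2 + 2 * r1 * t1 + t1^2) - r2
  after <- vessel_geometry(inner_radius = r2, wall_thickness = t2,
                           axial_stretch = geom$axial_stretch)
  structure(list(before = geom, after = after), class = "deformation_map")
}

#' @export
print.deformation_map <- function(x, ...) {
  cat(sprintf(
    "Area-conserving deformation map: inner diameter %.3f -> %.3f mm, thickness %.3f -> %.3f mm\n",
    2 * x$before$inner_radius, 2 * x$after$inner_radius,
    x$before$wall_thickness, x$after$wall_thickness))
  invisible(x)
}

#' Map a before-radius through a deformation map
#'
#' @param map a `deformation_map` from [dilate_area_conserving()].
#' @param radius_before radius in the before state, mm; must lie inside the
#'   before wall.
#' @return corresponding radius in the after state, mm.
#' @export
map_radius <- function(map, radius_before) {
  stopifnot(inherits(map, "deformation_map"))
  r1 <- map$before$inner_radius
  ro <- outer_radius(map$before)
  if (any(radius_before < r1 - 1e-9) || any(radius_before > ro + 1e-9)) {
    abort_validation(sprintf(
      "radius_before outside the before wall [%.4f, %.4f] mm", r1, ro),
      class = "smcdeform_range_error")
  }
  sqrt(map$after$inner_radius^2 + radius_before^2 - r1^2)
}

#' Local in-plane stretches of the wall under a deformation map
#'
#' Circumferential stretch `lambda_theta = r_after / r_before` and radial
#' stretch `lambda_r = d r_after / d r_before` at a material point. Under
#' area-conserving in-plane deformation with fixed axial stretch their
#' product is exactly 1, so a circumferentially oriented SMC nucleus has its
#' aspect ratio multiplied by `lambda_theta / lambda_r = lambda_theta^2`.
#'
#' @param map a `deformation_map`.
#' @param radius_before radius in the before state, mm.
#' @return a list with numeric vectors `lambda_theta` and `lambda_r`.
#' @export
local_stretch <- function(map, radius_before) {
  ra <- map_radius(map, radius_before)
  lt <- ra / radius_before
  list(lambda_theta = lt, lambda_r = radius_before / ra)
}

#' Transformation rate of the vessel wall
#'
#' The ratio of (inner diameter / wall thickness) after dilatation to the
#' same quantity before: the bulk measure of wall stretching against which
#' the SMC deformation rate is validated.
#'
#' @param before,after [vessel_geometry()] objects.
#' @return dimensionless transformation rate.
#' @examples
#' b <- vessel_geometry(inner_diameter = 1.46, wall_thickness = 0.54)
#' a <- dilate_area_conserving(b, 2.0)$after
#' transformation_rate(b, a)  # ~1.67
#' @export
transformation_rate <- function(before, after) {
  stopifnot(inherits(before, "vessel_geometry"),
            inherits(after, "vessel_geometry"))
  (2 * after$inner_radius / after$wall_thickness) /
    (2 * before$inner_radius / before$wall_thickness)
}

#' Ground-truth mean nuclear aspect multiplier of a deformation map
#'
#' Expected aspect-ratio multiplier `lambda_theta^2` of circumferentially
#' oriented nuclei distributed uniformly over the before-annulus area:
#' closed form `1 + 2 c ln(r_o/r_i) / (r_o^2 - r_i^2)` with
#' `c = r_i'^2 - r_i^2`. Used as an independent oracle for the synthetic
#' cohort's ground truth.
#'
#' @param map a `deformation_map`.
#' @return dimensionless mean multiplier.
#' @export
mean_aspect_multiplier <- function(map) {
  ri <- map$before$inner_radius
  ro <- outer_radius(map$before)
  cc <- map$after$inner_radius^2 - ri^2
  1 + 2 * cc * log(ro / ri) / (ro^2 - ri^2)
}
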