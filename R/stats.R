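#' Arterial dilatation rate, ex-vivo convention
#'
#' Inner diameter after dilatation divided by inner diameter before.
#'
#' @param d_after,d_before inner diameters, mm (both > 0).
#' @return dimensionless dilatation rate.
#' @export
dilatation_rate_ex_vivo <- function(d_after, d_before) {
  check_number(d_after, "d_after", positive = TRUE)
  check_number(d_before, "d_before", positive = TRUE)
  d_after / d_before
}

#' Arterial dilatation rate, in-vivo convention
#'
#' Square root of the dilated-segment luminal area divided by the control
#' (undilated) segment's luminal area. Agrees with the ex-vivo diameter
#' convention for circular lumens.
#'
#' @param area_dilated,area_control luminal areas, mm^2 (both > 0).
#' @return dimensionless dilatation rate.
#' @export
dilatation_rate_in_vivo <- function(area_dilated, area_control) {
  check_number(area_dilated, "area_dilated", positive = TRUE)
  check_number(area_control, "area_control", positive = TRUE)
  sqrt(area_dilated / area_control)
}

# media annulus mask: every sub-background pixel (tissue + nuclei)
media_mask <- function(img, background_cut = 0.9) {
  img <= background_cut
}

#' Media cross-sectional area measured from an image
#'
#' Pixel count of the media annulus (all sub-background pixels: tissue and
#' nuclei) corrected by the physical pixel size.
#'
#' @param image a `histology_image` or numeric matrix.
#' @param pixel_size mm per pixel (when `image` is a matrix).
#' @param background_cut intensity at/below which a pixel is tissue.
#' @return area, mm^2.
#' @export
media_area <- function(image, pixel_size = NULL, background_cut = 0.9) {
  im <- as_image_matrix(image, pixel_size)
  npx <- sum(media_mask(im$img, background_cut))
  if (npx == 0L) {
    abort_validation("no media annulus found in the image")
  }
  npx * im$pixel_size^2
}

#' After/before ratio of media cross-sectional area
#'
#' The area-conservation check: the media area measured from the after image
#' divided by that from the before image, each pixel-size corrected. Under
#' dilatation without plastic deformation this ratio stays at 1 (the study's
#' specimens stayed below 1.02).
#'
#' @param before,after `histology_image`s (or matrices, with
#'   `pixel_size_before` / `pixel_size_after`).
#' @param pixel_size_before,pixel_size_after mm per pixel for matrices.
#' @param background_cut intensity at/below which a pixel is tissue.
#' @return dimensionless area ratio.
#' @export
area_ratio <- function(before, after,
                       pixel_size_before = NULL, pixel_size_after = NULL,
                       background_cut = 0.9) {
  media_area(after, pixel_size_after, background_cut) /
    media_area(before, pixel_size_before, background_cut)
}

#' Luminal inner diameter measured from an image
#'
#' Identifies the lumen as the background-valued connected region containing
#' the image centre and converts its pixel area to the diameter of the
#' equivalent circle.
#'
#' @param image a `histology_image` or numeric matrix.
#' @param pixel_size mm per pixel (when `image` is a matrix).
#' @param background_cut intensity above which a pixel is background.
#' @return inner diameter, mm.
#' @export
measure_inner_diameter <- function(image, pixel_size = NULL,
                                   background_cut = 0.9) {
  im <- as_image_matrix(image, pixel_size)
  bg <- im$img > background_cut
  lab <- EBImage::imageData(EBImage::bwlabel(bg))
  centre <- lab[round(nrow(lab) / 2), round(ncol(lab) / 2)]
  if (centre == 0) {
    abort_validation("image centre is not background: no lumen found")
  }
  area <- sum(lab == centre) * im$pixel_size^2
  2 * sqrt(area / pi)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length (n >= 3, nonzero variance).
#' @return correlation coefficient r.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    abort_validation("`x` and `y` must have equal length")
  }
  if (length(x) < 3L) {
    abort_validation("at least 3 paired observations are required")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_validation("zero variance: correlation undefined")
  }
  stats::cor(x, y)
}

#' Two-sample t test
#'
#' Two-sided unpaired t test; classical Student (equal variances) by default,
#' matching the study's group comparisons, with Welch available by flag.
#'
#' @param group_a,group_b numeric vectors (n >= 2 each).
#' @param var_equal pool variances (Student) if `TRUE`, Welch otherwise.
#' @return list with `statistic`, `p_value`, `df`, `method`.
#' @export
two_sample_t_test <- function(group_a, group_b, var_equal = TRUE) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    abort_validation("each group needs at least 2 observations")
  }
  if (stats::var(group_a) + stats::var(group_b) == 0) {
    abort_validation("degenerate groups: zero variance in both")
  }
  tt <- stats::t.test(group_a, group_b, var.equal = var_equal)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), method = tt$method)
}
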