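#' Segmentation parameters for nuclei morphometry
#'
#' @param threshold_method `"automatic"` (Otsu threshold computed over the
#'   non-background pixels) or `"fixed"`.
#' @param threshold fixed intensity threshold (used when
#'   `threshold_method = "fixed"`); pixels strictly below it are foreground.
#' @param min_area,max_area connected-component area filter, px.
#' @param border_policy `"exclude-touching"` drops components touching the
#'   image border; `"include"` keeps them.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(threshold_method = c("automatic", "fixed"),
                                threshold = 0.5,
                                min_area = 30, max_area = Inf,
                                border_policy = c("exclude-touching",
                                                  "include")) {
  check_number(threshold, "threshold")
  check_number(min_area, "min_area", positive = TRUE)
  if (!(is.numeric(max_area) && length(max_area) == 1L && max_area > min_area)) {
    abort_validation("`max_area` must be a single number > `min_area`")
  }
  structure(list(threshold_method = match.arg(threshold_method),
                 threshold = threshold,
                 min_area = min_area, max_area = max_area,
                 border_policy = match.arg(border_policy)),
            class = "segmentation_params")
}

# pull (image matrix, pixel_size) out of a histology_image or matrix+arg
as_image_matrix <- function(image, pixel_size) {
  if (inherits(image, "histology_image")) {
    list(img = image$image, pixel_size = image$pixel_size)
  } else {
    stopifnot(is.matrix(image))
    check_number(pixel_size, "pixel_size", positive = TRUE)
    list(img = image, pixel_size = pixel_size)
  }
}

#' Segment nuclei from a grayscale histology image
#'
#' Thresholds the image (nuclei are dark) and labels connected components,
#' then applies the area filter and border policy. The automatic threshold is
#' Otsu's, computed over the sub-background pixels (tissue + nuclei) so the
#' white background does not dominate the histogram; if those pixels show no
#' contrast the image is treated as nucleus-free.
#'
#' @param image a [render_histology_image()] result, a
#'   [read_histology_image()] result, or a numeric matrix in \[0,1\].
#' @param pixel_size mm per pixel (taken from `image` when it is a
#'   `histology_image`).
#' @param params a [segmentation_params()].
#' @return an object of class `nuclei_segmentation`: list with `labels`
#'   (integer matrix, 0 = background), `n` regions, `pixel_size` and the
#'   threshold used. A warning is raised when no region is found.
#' @export
segment_nuclei <- function(image, pixel_size = NULL,
                           params = segmentation_params()) {
  im <- as_image_matrix(image, pixel_size)
  img <- im$img
  stopifnot(inherits(params, "segmentation_params"))

  if (params$threshold_method == "fixed") {
    thr <- params$threshold
  } else {
    # Two-stage automatic threshold for dark nuclei. Otsu on the whole image
    # separates the brightest mode (background, and tissue if present is
    # usually grouped with the nuclei side or split off next); if the
    # sub-threshold pixels still show contrast they contain both tissue and
    # nuclei and a second Otsu splits them. A contrast-free sub-threshold
    # class is accepted as nuclei only if it is dark (mean below half the
    # background intensity) -- otherwise it is bare tissue and there is
    # nothing to segment.
    otsu_vec <- function(v) {
      EBImage::otsu(EBImage::Image(matrix(v, ncol = 1L)), range = range(v))
    }
    bg <- max(img)
    if (diff(range(img)) < 1e-6) {
      thr <- -Inf
    } else {
      thr1 <- otsu_vec(as.vector(img))
      below <- img[img < thr1]
      if (length(below) < 2L) {
        thr <- -Inf
      } else if (diff(range(below)) >= 0.2) {
        thr <- otsu_vec(below)
      } else if (mean(below) < 0.5 * bg) {
        thr <- thr1
      } else {
        thr <- -Inf
      }
    }
  }

  binary <- img < thr
  labels <- matrix(0L, nrow(img), ncol(img))
  n_kept <- 0L
  if (any(binary)) {
    lab <- EBImage::imageData(EBImage::bwlabel(binary))
    storage.mode(lab) <- "integer"
    areas <- tabulate(lab)
    keep <- which(areas >= params$min_area & areas <= params$max_area)
    if (params$border_policy == "exclude-touching" && length(keep)) {
      on_border <- unique(c(lab[1L, ], lab[nrow(lab), ],
                            lab[, 1L], lab[, ncol(lab)]))
      keep <- setdiff(keep, on_border)
    }
    if (length(keep)) {
      remap <- integer(length(areas))
      remap[keep] <- seq_along(keep)
      pos <- which(lab > 0L)
      labels[pos] <- remap[lab[pos]]
      n_kept <- length(keep)
    }
  }
  if (n_kept == 0L) {
    warning("no nuclei segmented", call. = FALSE)
  }
  structure(list(labels = labels, n = n_kept, pixel_size = im$pixel_size,
                 threshold = thr, params = params),
            class = "nuclei_segmentation")
}

#' @export
print.nuclei_segmentation <- function(x, ...) {
  cat(sprintf("Nuclei segmentation: %d regions at %.4g mm/px (threshold %.3g)\n",
              x$n, x$pixel_size, x$threshold))
  invisible(x)
}

#' Fit an equivalent ellipse to a pixel region by second-order moments
#'
#' Axis lengths of the ellipse with the same second central moments as the
#' pixel set (the equivalent-ellipse convention: full axis = 4 sqrt(lambda)
#' for each eigenvalue lambda of the pixel covariance matrix), and the
#' orientation of the principal axis. This is the deterministic stand-in for
#' the study's manual long/short-axis measurement; for true ellipses the two
#' coincide in expectation.
#'
#' @param coords two-column matrix of pixel coordinates (row, col) -- as from
#'   `which(..., arr.ind = TRUE)`.
#' @param pixel_size mm per pixel.
#' @return one-row data frame: label, centroid_x_px, centroid_y_px,
#'   long_axis_mm, short_axis_mm, orientation_rad (angle of the major axis
#'   from the image x-axis, in (-pi/2, pi/2\]), aspect_ratio (long/short,
#'   >= 1).
#' @export
fit_ellipse <- function(coords, pixel_size) {
  check_number(pixel_size, "pixel_size", positive = TRUE)
  stopifnot(is.matrix(coords), ncol(coords) == 2L)
  n <- nrow(coords)
  if (n < 6L) {
    abort_validation(sprintf("region has %d pixels; at least 6 are required", n))
  }
  y <- coords[, 1L]
  x <- coords[, 2L]
  mx <- mean(x); my <- mean(y)
  dx <- x - mx; dy <- y - my
  mu20 <- mean(dx^2)
  mu02 <- mean(dy^2)
  mu11 <- mean(dx * dy)
  tr <- mu20 + mu02
  disc <- sqrt(max((mu20 - mu02)^2 + 4 * mu11^2, 0))
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  if (l2 <= 1e-12) {
    abort_validation("degenerate (collinear) region: cannot fit an ellipse",
                     class = "smcdeform_degenerate_error")
  }
  ang <- atan2(2 * mu11, mu20 - mu02) / 2
  if (ang <= -pi / 2) ang <- ang + pi
  if (ang > pi / 2) ang <- ang - pi
  long <- 4 * sqrt(l1) * pixel_size
  short <- 4 * sqrt(l2) * pixel_size
  data.frame(label = NA_integer_, centroid_x_px = mx, centroid_y_px = my,
             long_axis_mm = long, short_axis_mm = short,
             orientation_rad = ang, aspect_ratio = long / short)
}

#' Measure all segmented nuclei of an image
#'
#' Runs [fit_ellipse()] on every labelled region. Regions too small or
#' degenerate for a moment fit are dropped with a warning.
#'
#' @param seg a [segment_nuclei()] result, or an image (then segmentation is
#'   run first with `params`).
#' @param pixel_size,params passed to [segment_nuclei()] when `seg` is an
#'   image.
#' @return data frame of nucleus measurements (one row per region).
#' @export
measure_nuclei <- function(seg, pixel_size = NULL,
                           params = segmentation_params()) {
  if (!inherits(seg, "nuclei_segmentation")) {
    seg <- segment_nuclei(seg, pixel_size, params)
  }
  if (seg$n == 0L) {
    return(data.frame(label = integer(), centroid_x_px = numeric(),
                      centroid_y_px = numeric(), long_axis_mm = numeric(),
                      short_axis_mm = numeric(), orientation_rad = numeric(),
                      aspect_ratio = numeric()))
  }
  pos <- which(seg$labels > 0L)
  ids <- seg$labels[pos]
  rc <- arrayInd(pos, dim(seg$labels))
  rows_by_id <- split(seq_along(ids), ids)
  out <- vector("list", length(rows_by_id))
  dropped <- 0L
  for (k in seq_along(rows_by_id)) {
    idx <- rows_by_id[[k]]
    fit <- tryCatch(fit_ellipse(rc[idx, , drop = FALSE], seg$pixel_size),
                    error = function(e) NULL)
    if (is.null(fit)) {
      dropped <- dropped + 1L
    } else {
      fit$label <- as.integer(names(rows_by_id)[k])
      out[[k]] <- fit
    }
  }
  if (dropped > 0L) {
    warning(sprintf("%d region(s) dropped (too small or degenerate for a moment fit)",
                    dropped), call. = FALSE)
  }
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}

#' Summarise the nuclear aspect ratios of one specimen
#'
#' @param measurements data frame from [measure_nuclei()] (needs column
#'   `aspect_ratio`), or a numeric vector of aspect ratios.
#' @return an object of class `specimen_summary`: list with `n_nuclei`,
#'   `mean_aspect`, `sd_aspect`.
#' @export
summarize_specimen <- function(measurements) {
  ar <- if (is.data.frame(measurements)) measurements$aspect_ratio else measurements
  if (is.null(ar) || length(ar) == 0L) {
    abort_validation("no nucleus measurements to summarise")
  }
  structure(list(n_nuclei = length(ar), mean_aspect = mean(ar),
                 sd_aspect = if (length(ar) > 1L) stats::sd(ar) else 0),
            class = "specimen_summary")
}

#' @export
print.specimen_summary <- function(x, ...) {
  cat(sprintf("Specimen summary: %d nuclei, aspect ratio %.3f +/- %.3f\n",
              x$n_nuclei, x$mean_aspect, x$sd_aspect))
  invisible(x)
}

#' Deformation rate of SMC shape
#'
#' The study's deformation rate: the mean nuclear long/short axis ratio after
#' dilatation divided by that before dilatation. Before and after specimens
#' are different sections, so nuclei are pooled per state (ratio of means).
#' When raw measurements are supplied a nonparametric bootstrap over nuclei
#' (resampling each state independently) gives a percentile confidence
#' interval.
#'
#' @param after,before [summarize_specimen()] results, measurement data
#'   frames, or numeric vectors of aspect ratios.
#' @param n_boot bootstrap resamples (only used with raw measurements;
#'   default 1000; 0 disables).
#' @param conf_level confidence level for the percentile interval.
#' @param boot_seed seed for the bootstrap.
#' @return list with `rate` and, when bootstrapped, `ci` (length-2) and `se`.
#' @export
deformation_rate <- function(after, before, n_boot = 1000,
                             conf_level = 0.95, boot_seed = 1) {
  get_aspects <- function(x) {
    if (inherits(x, "specimen_summary")) return(NULL)
    if (is.data.frame(x)) return(x$aspect_ratio)
    if (is.numeric(x)) return(x)
    NULL
  }
  mean_of <- function(x) {
    if (inherits(x, "specimen_summary")) x$mean_aspect else mean(get_aspects(x))
  }
  a <- get_aspects(after)
  b <- get_aspects(before)
  rate <- mean_of(after) / mean_of(before)
  out <- list(rate = rate)
  if (!is.null(a) && !is.null(b) && n_boot > 0) {
    boots <- with_seed(boot_seed, {
      vapply(seq_len(n_boot), function(i) {
        mean(sample(a, replace = TRUE)) / mean(sample(b, replace = TRUE))
      }, 0)
    })
    alpha <- (1 - conf_level) / 2
    out$ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha)))
    out$se <- stats::sd(boots)
  }
  out
}
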