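#' Render a histology-like image of a vessel phantom
#'
#' Rasterises one state of a phantom as a grayscale cross-section: white
#' background (1.0), light media annulus (0.8), dark elliptical nuclei
#' (0.15) -- the contrast polarity of an HE-stained section where nuclei
#' stain dark. Multiplicative lognormal measurement noise (the phantom's
#' `measurement_noise_cv`, applied per nucleus axis) and the sub-pixel
#' placement of nucleus centres are applied at render time, so measured and
#' ground-truth axes differ by realistic measurement error.
#'
#' @param phantom a [generate_phantom()] object.
#' @param which `"before"` or `"after"`.
#' @param pixel_size mm per pixel. `NULL` (default) picks automatically so
#'   the smallest nuclear short axis spans 8 pixels (capped at 0.001 mm/px).
#'   An explicit value letting any short axis span fewer than 6 pixels is
#'   rejected, preventing silent morphometry bias.
#' @return an object of class `histology_image`: list with `image` (matrix in
#'   \[0,1\], rows = y), `pixel_size` (mm/px), `which`, `specimen_id` and the
#'   ground-truth `truth` data frame.
#' @export
render_histology_image <- function(phantom, which = c("before", "after"),
                                   pixel_size = NULL) {
  stopifnot(inherits(phantom, "vessel_phantom"))
  which <- match.arg(which)
  geom <- if (which == "before") phantom$geometry_before else phantom$geometry_after
  nuclei <- if (which == "before") phantom$nuclei_before else phantom$nuclei_after

  if (nrow(nuclei) > 0L) {
    min_short <- min(nuclei$short_axis_mm)
    if (is.null(pixel_size)) {
      pixel_size <- min(0.001, min_short / 8)
    } else if (min_short / pixel_size < 6) {
      abort_validation(sprintf(
        "pixel_size %.4g mm/px too coarse: smallest nuclear short axis (%.4g mm) spans %.1f px < 6",
        pixel_size, min_short, min_short / pixel_size),
        class = "smcdeform_resolution_error")
    }
  } else if (is.null(pixel_size)) {
    pixel_size <- 0.001
  }
  check_number(pixel_size, "pixel_size", positive = TRUE)

  ro <- outer_radius(geom)
  half <- ro * 1.03 + 3 * pixel_size
  n <- as.integer(ceiling(2 * half / pixel_size))
  coord <- (seq_len(n) - 0.5) * pixel_size - half  # pixel-centre coordinates
  img <- matrix(1, n, n)  # rows = y, cols = x
  r2 <- outer(coord^2, coord^2, `+`)
  img[r2 >= geom$inner_radius^2 & r2 <= ro^2] <- 0.8
  rm(r2)

  if (nrow(nuclei) > 0L) {
    sdlog <- sqrt(log(1 + phantom$measurement_noise_cv^2))
    with_seed(phantom$seed * 2L + (which == "after"), {
      noise_l <- exp(stats::rnorm(nrow(nuclei), 0, sdlog))
      noise_s <- exp(stats::rnorm(nrow(nuclei), 0, sdlog))
      for (j in seq_len(nrow(nuclei))) {
        a <- nuclei$long_axis_mm[j] * noise_l[j] / 2
        b <- nuclei$short_axis_mm[j] * noise_s[j] / 2
        r <- nuclei$centroid_r_mm[j]
        th <- nuclei$centroid_theta_rad[j]
        # absolute orientation: local circumferential direction plus jitter
        phi <- th + pi / 2 + nuclei$orientation_rad[j]
        cx <- r * cos(th)
        cy <- r * sin(th)
        ext <- a + 2 * pixel_size
        cols <- which(coord >= cx - ext & coord <= cx + ext)
        rows <- which(coord >= cy - ext & coord <= cy + ext)
        dx <- coord[cols] - cx
        dy <- coord[rows] - cy
        u <- outer(dy * sin(phi), dx * cos(phi), `+`)       # along major axis
        v <- outer(dy * cos(phi), -dx * sin(phi), `+`)      # along minor axis
        inside <- (u / a)^2 + (v / b)^2 <= 1
        img[rows, cols][inside] <- 0.15
      }
    })
  }

  structure(list(image = img, pixel_size = pixel_size, which = which,
                 specimen_id = phantom$specimen_id, truth = nuclei),
            class = "histology_image")
}

#' @export
print.histology_image <- function(x, ...) {
  cat(sprintf(
    "Histology image (%s, %s): %d x %d px at %.4g mm/px, %d ground-truth nuclei\n",
    x$specimen_id %||% "?", x$which, nrow(x$image), ncol(x$image),
    x$pixel_size, nrow(x$truth)))
  invisible(x)
}

#' @export
plot.histology_image <- function(x, ...) {
  graphics::image(t(x$image)[, nrow(x$image):1], col = grDevices::gray.colors(64, 0, 1),
                  asp = 1, axes = FALSE, ...)
  invisible(x)
}

#' Write a histology image to TIFF or PNG with a pixel-size sidecar
#'
#' Writes the grayscale image (8-bit by default for PNG, 8- or 16-bit for
#' TIFF) and records the physical pixel size in a JSON sidecar
#' `<path>.json` as `{"pixel_size_mm": ...}`.
#'
#' @param x a `histology_image`.
#' @param path output path ending in `.tif`, `.tiff` or `.png`.
#' @param bits bits per sample for TIFF (8 or 16).
#' @return `path`, invisibly.
#' @export
write_histology_image <- function(x, path, bits = 8) {
  stopifnot(inherits(x, "histology_image"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(x$image, path, bits.per.sample = bits)
  } else if (ext == "png") {
    png::writePNG(x$image, path)
  } else {
    abort_validation("unsupported image format (use .tif, .tiff or .png)")
  }
  jsonlite::write_json(list(pixel_size_mm = x$pixel_size),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a grayscale image plus its pixel-size sidecar
#'
#' Reads a single-channel TIFF/PNG (multi-channel images are averaged to
#' grayscale) and its `<path>.json` sidecar; the pixel size may also be given
#' directly.
#'
#' @param path image path.
#' @param pixel_size mm per pixel; overrides the sidecar.
#' @return a `histology_image` (with an empty `truth` table).
#' @export
read_histology_image <- function(path, pixel_size = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext == "png") {
    png::readPNG(path)
  } else {
    abort_validation("unsupported image format (use .tif, .tiff or .png)")
  }
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  if (is.null(pixel_size)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) {
      abort_validation(sprintf(
        "no pixel size given and sidecar %s not found", sidecar))
    }
    pixel_size <- jsonlite::read_json(sidecar)$pixel_size_mm
  }
  check_number(pixel_size, "pixel_size", positive = TRUE)
  structure(list(image = img, pixel_size = pixel_size, which = NA_character_,
                 specimen_id = NA_character_,
                 truth = data.frame()),
            class = "histology_image")
}
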