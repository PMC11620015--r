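#' Scan geometry
#'
#' Describes the lateral raster of an en-face scan: pixel grid size, one
#' isotropic lateral pixel spacing in micrometres, and the fovea location.
#' The coordinate convention throughout the package is `(row, col)`,
#' 0-based, with pixel centers at integer coordinates; all micrometre to
#' pixel conversions go through `pixel_spacing_um`.
#'
#' @param width_px,height_px Image size in pixels (columns, rows).
#' @param pixel_spacing_um Lateral pixel spacing in micrometres, identical
#'   on both axes (the nominal 6-mm x 6-mm pattern has 12 um spacing).
#' @param fovea_px Numeric `(row, col)` location of the fovea, 0-based.
#' @param nominal_fov_mm Nominal field of view in mm; computed from
#'   `width_px * pixel_spacing_um / 1000` when omitted, and required to
#'   agree with it within 1% when supplied.
#' @return An object of class `scan_geometry`.
#' @export
scan_geometry <- function(width_px, height_px, pixel_spacing_um,
                          fovea_px = c((height_px - 1) / 2, (width_px - 1) / 2),
                          nominal_fov_mm = NULL) {
  width_px <- as.integer(width_px)
  height_px <- as.integer(height_px)
  stopifnot(width_px > 0L, height_px > 0L)
  if (length(pixel_spacing_um) != 1L || !is.finite(pixel_spacing_um) ||
      pixel_spacing_um <= 0) {
    stop("pixel_spacing_um must be a single positive number ",
         "(anisotropic spacing is not supported)", call. = FALSE)
  }
  fovea_px <- as.numeric(fovea_px)
  if (length(fovea_px) != 2L || anyNA(fovea_px)) {
    stop("fovea_px must be a numeric (row, col) pair", call. = FALSE)
  }
  if (fovea_px[1L] < 0 || fovea_px[1L] > height_px - 1 ||
      fovea_px[2L] < 0 || fovea_px[2L] > width_px - 1) {
    stop("fovea_px lies outside the image bounds", call. = FALSE)
  }
  fov <- width_px * pixel_spacing_um / 1000
  if (is.null(nominal_fov_mm)) {
    nominal_fov_mm <- fov
  } else if (abs(nominal_fov_mm - fov) > 0.01 * fov) {
    stop(sprintf("nominal_fov_mm (%g) disagrees with width * spacing (%g mm) by more than 1%%",
                 nominal_fov_mm, fov), call. = FALSE)
  }
  structure(
    list(width_px = width_px, height_px = height_px,
         pixel_spacing_um = as.numeric(pixel_spacing_um),
         fovea_px = fovea_px, nominal_fov_mm = as.numeric(nominal_fov_mm)),
    class = "scan_geometry"
  )
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("<scan_geometry> %d x %d px, %.3g um/px (%.3g mm FOV), fovea (%.1f, %.1f)\n",
              x$height_px, x$width_px, x$pixel_spacing_um, x$nominal_fov_mm,
              x$fovea_px[1L], x$fovea_px[2L]))
  invisible(x)
}

same_geometry <- function(a, b) {
  a$width_px == b$width_px && a$height_px == b$height_px &&
    isTRUE(all.equal(a$pixel_spacing_um, b$pixel_spacing_um))
}

check_geometry_match <- function(a, b, what = "images") {
  if (!same_geometry(a, b)) {
    stop(sprintf("geometry mismatch between %s", what), call. = FALSE)
  }
  invisible(TRUE)
}

#' Convert micrometres to pixels and back
#'
#' @param um,px Length in micrometres / pixels.
#' @param geometry A [scan_geometry()].
#' @return Numeric length in the other unit.
#' @export
um_to_px <- function(um, geometry) um / geometry$pixel_spacing_um

#' @rdname um_to_px
#' @export
px_to_um <- function(px, geometry) px * geometry$pixel_spacing_um
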