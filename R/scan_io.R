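#' Scan metadata
#'
#' Identifies a scan within a dataset: patient, eye, visit, repeat index
#' within the visit, instrument signal strength (0-10) and study group.
#'
#' @param patient_id,eye_id,visit_id Identifier strings.
#' @param repeat_index Integer >= 1, the position within the same-day
#'   repeat series.
#' @param signal_strength Integer 0-10 reported by the instrument.
#' @param group_label One of `"normal"`, `"iAMD"`, `"hyperTD"`,
#'   `"unspecified"`.
#' @param acquisition_date Optional ISO date string.
#' @return An object of class `scan_metadata`.
#' @export
scan_metadata <- function(patient_id, eye_id, visit_id, repeat_index = 1L,
                          signal_strength = NA_integer_,
                          group_label = c("unspecified", "normal", "iAMD", "hyperTD"),
                          acquisition_date = NULL) {
  group_label <- match.arg(group_label)
  repeat_index <- as.integer(repeat_index)
  stopifnot(repeat_index >= 1L)
  if (!is.na(signal_strength)) {
    signal_strength <- as.integer(signal_strength)
    stopifnot(signal_strength >= 0L, signal_strength <= 10L)
  }
  structure(
    list(patient_id = as.character(patient_id),
         eye_id = as.character(eye_id),
         visit_id = as.character(visit_id),
         repeat_index = repeat_index,
         signal_strength = signal_strength,
         group_label = group_label,
         acquisition_date = acquisition_date),
    class = "scan_metadata"
  )
}

ENFACE_CHANNELS <- c("cc_flow", "cc_structure", "retinal_vasculature", "sub_rpe")
MASK_KINDS <- c("hrf", "cad", "hypertd", "peripapillary", "vitreous_shadow",
                "vessel_projection", "combined", "integrated", "validity")

#' En-face image
#'
#' A single-channel 2D intensity raster plus its [scan_geometry()].
#' Pixel values are stored as non-negative reals; 8/16-bit integer rasters
#' read from disk are preserved losslessly.
#'
#' @param pixels Numeric matrix (rows x cols), finite and non-negative.
#' @param geometry A [scan_geometry()] matching the matrix dimensions.
#' @param channel Which en-face slab/channel this raster represents.
#' @param metadata Optional [scan_metadata()].
#' @return An object of class `enface_image`.
#' @export
enface_image <- function(pixels, geometry,
                         channel = c("cc_flow", "cc_structure",
                                     "retinal_vasculature", "sub_rpe"),
                         metadata = NULL) {
  channel <- match.arg(channel)
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) != geometry$height_px || ncol(pixels) != geometry$width_px) {
    stop("pixel raster dimensions do not match geometry", call. = FALSE)
  }
  if (!all(is.finite(pixels))) stop("pixel values must be finite", call. = FALSE)
  if (min(pixels) < 0) stop("pixel values must be non-negative", call. = FALSE)
  structure(list(pixels = pixels, geometry = geometry, channel = channel,
                 metadata = metadata),
            class = "enface_image")
}

#' @export
print.enface_image <- function(x, ...) {
  cat(sprintf("<enface_image:%s> %d x %d px, range [%.3g, %.3g]\n",
              x$channel, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Binary mask
#'
#' A 2D logical raster tied to a [scan_geometry()]. For exclusion masks
#' (`role = "exclusion"`) `TRUE` marks pixels removed from analysis; for
#' validity/ROI masks (`role = "validity"`) `TRUE` marks usable pixels.
#'
#' @param pixels Logical matrix (rows x cols).
#' @param geometry A [scan_geometry()].
#' @param kind Lesion/mask kind; see `MASK_KINDS` in the source.
#' @param role `"exclusion"` or `"validity"`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, geometry, kind = "combined",
                        role = c("exclusion", "validity")) {
  role <- match.arg(role)
  kind <- match.arg(kind, MASK_KINDS)
  pixels <- as.matrix(pixels)
  if (!is.logical(pixels)) {
    stop("mask pixels must be logical", call. = FALSE)
  }
  if (nrow(pixels) != geometry$height_px || ncol(pixels) != geometry$width_px) {
    stop("mask dimensions do not match geometry", call. = FALSE)
  }
  if (kind %in% c("validity")) role <- "validity"
  structure(list(pixels = pixels, geometry = geometry, kind = kind, role = role),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask:%s/%s> %d x %d px, %d TRUE (%.2f%%)\n",
              x$kind, x$role, nrow(x$pixels), ncol(x$pixels),
              sum(x$pixels), 100 * mean(x$pixels)))
  invisible(x)
}

empty_mask <- function(geometry, kind = "combined", role = "exclusion") {
  binary_mask(matrix(FALSE, geometry$height_px, geometry$width_px),
              geometry, kind = kind, role = role)
}

#' Volumetric OCTA scan
#'
#' Paired flow and structure voxel rasters (`rows x cols x depth`), the
#' axial voxel spacing, and the Bruch's membrane surface as a per-pixel
#' depth index (0-based) from which en-face slabs are offset.
#'
#' @param flow_voxels,structure_voxels 3D non-negative numeric arrays of
#'   identical shape.
#' @param axial_spacing_um Axial voxel spacing in micrometres.
#' @param bm_surface_px Integer matrix of BM depth indices (0-based),
#'   one per (row, col).
#' @param geometry A [scan_geometry()] for the lateral raster.
#' @return An object of class `volume_scan`.
#' @export
volume_scan <- function(flow_voxels, structure_voxels, axial_spacing_um,
                        bm_surface_px, geometry) {
  stopifnot(length(dim(flow_voxels)) == 3L,
            identical(dim(flow_voxels), dim(structure_voxels)),
            axial_spacing_um > 0)
  d <- dim(flow_voxels)
  if (d[1L] != geometry$height_px || d[2L] != geometry$width_px) {
    stop("volume lateral dimensions do not match geometry", call. = FALSE)
  }
  bm_surface_px <- as.matrix(bm_surface_px)
  if (!identical(dim(bm_surface_px), d[1:2])) {
    stop("bm_surface_px dimensions do not match the volume", call. = FALSE)
  }
  if (min(bm_surface_px) < 0 || max(bm_surface_px) > d[3L] - 1L) {
    stop("bm_surface_px indices outside the volume depth range", call. = FALSE)
  }
  structure(list(flow_voxels = flow_voxels, structure_voxels = structure_voxels,
                 axial_spacing_um = as.numeric(axial_spacing_um),
                 bm_surface_px = bm_surface_px, geometry = geometry),
            class = "volume_scan")
}

# ---- raster + sidecar I/O -------------------------------------------------

read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!file.exists(path)) stop(sprintf("raster file not found: %s", path), call. = FALSE)
  px <- switch(ext,
    "tif" = , "tiff" = tiff::readTIFF(path, as.is = TRUE),
    "png" = {
      x <- png::readPNG(path)
      # readPNG scales to [0,1]; recover integer levels from bit depth
      info <- attr(x, "info")
      bits <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
      round(x * (2^bits - 1))
    },
    stop(sprintf("unsupported raster format '%s' (use TIFF or PNG)", ext),
         call. = FALSE)
  )
  if (length(dim(px)) == 3L) {
    if (dim(px)[3L] == 1L) px <- px[, , 1L]
    else stop("multi-channel raster: expected single-channel grayscale",
              call. = FALSE)
  }
  storage.mode(px) <- "double"
  px
}

write_raster <- function(pixels, path, bits = 16L) {
  ext <- tolower(tools::file_ext(path))
  maxv <- 2^bits - 1
  if (min(pixels) < 0 || max(pixels) > maxv) {
    stop(sprintf("pixel values outside the %d-bit range [0, %d]", bits, maxv),
         call. = FALSE)
  }
  scaled <- pixels / maxv
  switch(ext,
    "tif" = , "tiff" = tiff::writeTIFF(scaled, path, bits.per.sample = bits),
    "png" = {
      if (bits != 8L) {
        stop("PNG output supports 8-bit only; use TIFF for 16-bit rasters",
             call. = FALSE)
      }
      png::writePNG(scaled, path)
    },
    stop(sprintf("unsupported raster format '%s'", ext), call. = FALSE)
  )
  invisible(path)
}

SIDECAR_KNOWN_KEYS <- c("pixel_spacing_um", "fovea_px", "nominal_fov_mm",
                        "channel", "kind", "patient_id", "eye_id", "visit_id",
                        "repeat_index", "signal_strength", "group_label",
                        "acquisition_date", "width_px", "height_px")

read_sidecar <- function(sidecar, required = c("pixel_spacing_um", "fovea_px")) {
  if (!file.exists(sidecar)) {
    stop(sprintf("sidecar file not found: %s", sidecar), call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    stop(sprintf("sidecar %s is missing required field(s): %s",
                 basename(sidecar), paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  unknown <- setdiff(names(meta), SIDECAR_KNOWN_KEYS)
  if (length(unknown)) {
    warning(sprintf("ignoring unknown sidecar key(s): %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }
  meta
}

sidecar_metadata <- function(meta) {
  if (is.null(meta$patient_id)) return(NULL)
  scan_metadata(
    patient_id = meta$patient_id,
    eye_id = if (is.null(meta$eye_id)) meta$patient_id else meta$eye_id,
    visit_id = if (is.null(meta$visit_id)) "v1" else meta$visit_id,
    repeat_index = if (is.null(meta$repeat_index)) 1L else meta$repeat_index,
    signal_strength = if (is.null(meta$signal_strength)) NA_integer_ else meta$signal_strength,
    group_label = if (is.null(meta$group_label)) "unspecified" else meta$group_label,
    acquisition_date = meta$acquisition_date
  )
}

#' Read an en-face image with its JSON sidecar
#'
#' Reads a single-channel 8/16-bit grayscale TIFF or PNG raster and a JSON
#' sidecar carrying the scan geometry (`pixel_spacing_um`, `fovea_px`) and
#' optional metadata. Pixel values are preserved losslessly as reals.
#'
#' @param path Path to the raster.
#' @param sidecar Path to the JSON sidecar.
#' @param channel Channel override; defaults to the sidecar's `channel`
#'   field, or `"cc_flow"` when absent.
#' @return An [enface_image()].
#' @seealso [write_enface()]
#' @export
read_enface <- function(path, sidecar, channel = NULL) {
  px <- read_raster(path)
  meta <- read_sidecar(sidecar)
  geom <- scan_geometry(
    width_px = ncol(px), height_px = nrow(px),
    pixel_spacing_um = meta$pixel_spacing_um,
    fovea_px = as.numeric(meta$fovea_px),
    nominal_fov_mm = meta$nominal_fov_mm
  )
  if (is.null(channel)) {
    channel <- if (!is.null(meta$channel)) meta$channel else "cc_flow"
  }
  enface_image(px, geom, channel = channel, metadata = sidecar_metadata(meta))
}

#' Write an en-face image and its JSON sidecar
#'
#' @param img An [enface_image()].
#' @param path Output raster path (`.tif`/`.tiff`, or `.png` for 8-bit).
#' @param sidecar Output sidecar path; defaults to `path` with a `.json`
#'   extension.
#' @param bits Bit depth, 8 or 16 (default).
#' @return `path`, invisibly.
#' @export
write_enface <- function(img, path, sidecar = paste0(tools::file_path_sans_ext(path), ".json"),
                         bits = 16L) {
  write_raster(img$pixels, path, bits = bits)
  sc <- list(pixel_spacing_um = img$geometry$pixel_spacing_um,
             fovea_px = img$geometry$fovea_px,
             nominal_fov_mm = img$geometry$nominal_fov_mm,
             channel = img$channel)
  if (!is.null(img$metadata)) {
    sc <- c(sc, unclass(img$metadata)[!vapply(unclass(img$metadata), is.null, TRUE)])
  }
  jsonlite::write_json(sc, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a binary mask raster
#'
#' Mask rasters must be strictly binary: every pixel either 0 or the
#' raster's maximum value. Nonzero pixels map to `TRUE`.
#'
#' @param path Raster path.
#' @param sidecar JSON sidecar path (geometry).
#' @param kind Mask kind (e.g. `"hrf"`, `"cad"`, `"hypertd"`).
#' @param role `"exclusion"` (default) or `"validity"`.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, sidecar, kind, role = "exclusion") {
  px <- read_raster(path)
  vals <- sort(unique(as.vector(px)))
  if (length(vals) > 2L || (length(vals) == 2L && vals[1L] != 0)) {
    stop(sprintf("mask raster %s is not binary (values: %s)", basename(path),
                 paste(utils::head(vals, 5), collapse = ", ")), call. = FALSE)
  }
  meta <- read_sidecar(sidecar)
  geom <- scan_geometry(ncol(px), nrow(px), meta$pixel_spacing_um,
                        as.numeric(meta$fovea_px), meta$nominal_fov_mm)
  binary_mask(px > 0, geom, kind = kind, role = role)
}

#' Write a binary mask raster (8-bit, 0/255) plus sidecar
#'
#' @param mask A [binary_mask()].
#' @param path Output raster path.
#' @param sidecar Output sidecar path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path,
                       sidecar = paste0(tools::file_path_sans_ext(path), ".json")) {
  write_raster(matrix(ifelse(mask$pixels, 255, 0), nrow(mask$pixels)),
               path, bits = 8L)
  jsonlite::write_json(
    list(pixel_spacing_um = mask$geometry$pixel_spacing_um,
         fovea_px = mask$geometry$fovea_px,
         nominal_fov_mm = mask$geometry$nominal_fov_mm,
         kind = mask$kind),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Scan quality control
#'
#' A scan fails QC when its signal strength is below 7 or when the
#' operator flagged significant motion artifacts or insufficient
#' illumination. All failure reasons are enumerated.
#'
#' @param meta A [scan_metadata()] with `signal_strength` present.
#' @param flags Character vector of operator flags; recognised values are
#'   `"motion"` and `"insufficient_illumination"`.
#' @return A list with `pass` (logical) and `reasons` (character vector,
#'   empty iff `pass`).
#' @export
qc_check <- function(meta, flags = character()) {
  if (is.na(meta$signal_strength)) {
    stop("signal_strength is required for QC", call. = FALSE)
  }
  reasons <- character()
  if (meta$signal_strength < 7L) reasons <- c(reasons, "signal_strength<7")
  if ("motion" %in% flags) reasons <- c(reasons, "motion")
  if ("insufficient_illumination" %in% flags) {
    reasons <- c(reasons, "insufficient_illumination")
  }
  unknown <- setdiff(flags, c("motion", "insufficient_illumination"))
  if (length(unknown)) {
    warning(sprintf("ignoring unknown QC flag(s): %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}
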